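#include <Rcpp.h>
using namespace Rcpp;

// Stable log(plogis(x)) and log(1 - plogis(x)).
static inline double log_plogis(double x) {
  return (x > 0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}
static inline double log1m_plogis(double x) { return log_plogis(-x); }

// Marginal log-likelihood of the two-part occupancy/detection model.
//
// Square i: logit(psi_i) = a0 + a1 * firstAtlas_i.
// Visit k in square i: logit(p_ik) = b0 + b1*effort + b2*I(over50) + b3*I(male).
// Latent occupancy z_i is summed out exactly:
//   L_i = psi_i * prod_k Bern(y_ik | p_ik) + (1 - psi_i) * I(all y_i = 0).
//
// params = (a0, a1, b0, b1, b2, b3); square is 0-based and visits may appear
// in any order; first_atlas has one entry per square.
// [[Rcpp::export]]
double occu_loglik_cpp(NumericVector params,
                       IntegerVector square,
                       IntegerVector y,
                       NumericVector effort,
                       IntegerVector over50,
                       IntegerVector male,
                       IntegerVector first_atlas) {
  const int n = square.size();
  const int S = first_atlas.size();
  const double a0 = params[0], a1 = params[1];
  const double b0 = params[2], b1 = params[3], b2 = params[4], b3 = params[5];

  std::vector<double> det_lp(S, 0.0); // sum_k log Bern(y_ik | p_ik)
  std::vector<int> any_det(S, 0);

  for (int k = 0; k < n; ++k) {
    const int i = square[k];
    const double lp = b0 + b1 * effort[k] + b2 * over50[k] + b3 * male[k];
    if (y[k] == 1) {
      det_lp[i] += log_plogis(lp);
      any_det[i] = 1;
    } else {
      det_lp[i] += log1m_plogis(lp);
    }
  }

  double ll = 0.0;
  for (int i = 0; i < S; ++i) {
    const double lpsi = a0 + a1 * first_atlas[i];
    const double log_psi = log_plogis(lpsi);
    const double occ_term = log_psi + det_lp[i];
    if (any_det[i]) {
      ll += occ_term;
    } else {
      // log(psi * prod(1-p) + (1 - psi)), stably
      const double log_1mpsi = log1m_plogis(lpsi);
      const double m = std::max(occ_term, log_1mpsi);
      ll += m + std::log(std::exp(occ_term - m) + std::exp(log_1mpsi - m));
    }
  }
  return ll;
}

// One chain of adaptive Metropolis-within-Gibbs on the marginalized posterior.
// Independent Normal(0, prior_sd) priors on every coordinate. Coordinates with
// fixed[j] == TRUE are never updated (used for reduction/identifiability
// checks). Proposal scales adapt toward ~44% acceptance during the first
// adapt_until iterations only, so the retained chain is a valid Markov chain.
// Uses R's RNG: seeding with set.seed() in R makes chains reproducible.
// [[Rcpp::export]]
NumericMatrix occu_mcmc_chain_cpp(IntegerVector square,
                                  IntegerVector y,
                                  NumericVector effort,
                                  IntegerVector over50,
                                  IntegerVector male,
                                  IntegerVector first_atlas,
                                  int n_iter,
                                  NumericVector init,
                                  double prior_sd,
                                  LogicalVector fixed,
                                  double scale_init,
                                  int adapt_until) {
  const int P = 6;
  NumericMatrix draws(n_iter, P);
  NumericVector cur = clone(init);
  std::vector<double> scale(P, scale_init);
  std::vector<int> acc(P, 0), tries(P, 0);

  double cur_ll = occu_loglik_cpp(cur, square, y, effort, over50, male, first_atlas);
  const double pv = prior_sd * prior_sd;
  double cur_lprior = 0.0;
  for (int j = 0; j < P; ++j) cur_lprior += -0.5 * cur[j] * cur[j] / pv;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < P; ++j) {
      if (fixed[j]) continue;
      const double old = cur[j];
      cur[j] = old + R::norm_rand() * scale[j];
      const double prop_ll =
          occu_loglik_cpp(cur, square, y, effort, over50, male, first_atlas);
      const double prop_lprior =
          cur_lprior + 0.5 * (old * old - cur[j] * cur[j]) / pv;
      const double lr = (prop_ll + prop_lprior) - (cur_ll + cur_lprior);
      ++tries[j];
      if (std::log(R::unif_rand()) < lr) {
        cur_ll = prop_ll;
        cur_lprior = prop_lprior;
        ++acc[j];
      } else {
        cur[j] = old;
      }
    }
    if (it < adapt_until && (it + 1) % 50 == 0) {
      for (int j = 0; j < P; ++j) {
        if (tries[j] == 0) continue;
        const double rate = (double)acc[j] / tries[j];
        scale[j] *= std::exp(rate - 0.44);
        scale[j] = std::min(std::max(scale[j], 1e-4), 50.0);
        acc[j] = 0;
        tries[j] = 0;
      }
    }
    for (int j = 0; j < P; ++j) draws(it, j) = cur[j];
  }
  return draws;
}
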