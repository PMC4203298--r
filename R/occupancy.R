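#' Marginal log-likelihood of the occupancy/detection model
#'
#' Two-part hierarchical model for atlas detection histories. Per square `i`,
#' occupancy is Bernoulli with `logit(psi_i) = alpha0 + alpha1 * firstAtlas_i`
#' (detection in the previous atlas raises the occupancy prior); per visit
#' `k`, detection is Bernoulli conditional on occupancy with
#' `logit(p_ik) = beta0 + beta1 * effort_ik + beta2 * I(over50_ik) +
#' beta3 * I(male_ik)`. The latent occupancy state is marginalized exactly:
#' a square with any detection contributes `psi_i * prod_k Bern(y_ik|p_ik)`,
#' an all-zero square adds `(1 - psi_i)`.
#'
#' `beta2` is the quantity of interest: the logit-scale difference in
#' detection probability between observers over 50 and under 40 (negative
#' means older observers detect less).
#'
#' @param params Named numeric vector with `alpha0`, `alpha1`, `beta0`,
#'   `beta1`, `beta2`, `beta3` (all finite).
#' @param detections Detection data.frame with columns `square`, `effort`,
#'   `age_class` (`under40`/`mid`/`over50`), `gender`, `detected`,
#'   `first_atlas` (constant within square). Effort is used as supplied.
#' @return The marginal log-likelihood (scalar).
#' @examples
#' sim <- simulate_atlas(atlas_sim_config(n_squares = 10, seed = 1))
#' occu_loglik(c(alpha0 = 0, alpha1 = 0, beta0 = 0, beta1 = 0,
#'               beta2 = 0, beta3 = 0), sim$detections)
#' @export
occu_loglik <- function(params, detections) {
  params <- params[c("alpha0", "alpha1", "beta0", "beta1", "beta2", "beta3")]
  if (length(params) != 6 || any(is.na(params)) || any(!is.finite(params))) {
    stop("`params` must be 6 finite named coefficients ",
         "(alpha0, alpha1, beta0, beta1, beta2, beta3)")
  }
  d <- occu_prepare(detections, standardize_effort = FALSE)
  occu_loglik_cpp(as.numeric(params), d$square0, d$y, d$effort, d$over50,
                  d$male, d$first_atlas)
}

# Validate and index a detection table for the likelihood/sampler.
# Squares with fewer than 2 visit-years are dropped (the survey design
# requires at least two replicate years per square).
occu_prepare <- function(detections, standardize_effort = TRUE,
                         log_effort = FALSE) {
  req <- c("square", "effort", "age_class", "gender", "detected",
           "first_atlas")
  miss <- setdiff(req, names(detections))
  if (length(miss)) stop("detections missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(detections) == 0) stop("empty detection data")
  if (any(detections$effort <= 0)) {
    stop("zero/negative effort records present; exclude them upstream")
  }
  nv <- table(detections$square)
  keep <- names(nv)[nv >= 2]
  if (length(keep) < length(nv)) {
    detections <- detections[detections$square %in% keep, , drop = FALSE]
    if (nrow(detections) == 0) stop("no square has >= 2 visit-years")
  }
  sq <- factor(detections$square)
  fa <- tapply(detections$first_atlas, sq, function(v) v[1])
  if (any(tapply(detections$first_atlas, sq,
                 function(v) length(unique(v))) > 1)) {
    stop("`first_atlas` must be constant within a square")
  }
  eff <- detections$effort
  if (log_effort) eff <- log(eff)
  es <- c(mean = mean(eff), sd = sd(eff))
  if (standardize_effort) {
    eff <- if (es["sd"] > 0) (eff - es["mean"]) / es["sd"] else eff - es["mean"]
  }
  list(square0 = as.integer(sq) - 1L,
       y = as.integer(detections$detected),
       effort = as.numeric(eff),
       over50 = as.integer(detections$age_class == "over50"),
       male = as.integer(detections$gender == "male"),
       first_atlas = as.integer(fa),
       n_squares = nlevels(sq),
       effort_scaling = es,
       n_detections = sum(detections$detected))
}

#' MCMC settings for the occupancy model
#'
#' @param include_mid_age If `FALSE` (the primary analysis), visits by
#'   mid-aged (40-50) observers are dropped before fitting, so the age
#'   contrast compares under-40 with over-50 observers. If `TRUE` (the
#'   sensitivity refit), mid-aged observers are retained and join the
#'   "young" class, keeping the age-50 cutoff.
#' @param prior_sd Scale of the independent zero-centred Normal priors on all
#'   six coefficients (minimally informative default 10).
#' @param n_chains,n_iter,burn_in,thin Chain settings; `n_iter` must exceed
#'   `burn_in`.
#' @param log_effort Model log(effort) instead of effort (both standardized).
#' @param min_detections Minimum total detections required to fit a species.
#' @param enforce_min_detections Set `FALSE` to override the gate.
#' @param seed Integer seed (chain `c` uses `seed + c - 1`).
#' @return A list of class `"occu_model_spec"`.
#' @export
occu_model_spec <- function(include_mid_age = FALSE, prior_sd = 10,
                            n_chains = 3, n_iter = 20000,
                            burn_in = n_iter %/% 2, thin = 1,
                            log_effort = FALSE, min_detections = 100,
                            enforce_min_detections = TRUE, seed = 1L) {
  stopifnot(prior_sd > 0, n_chains >= 1, n_iter > burn_in, burn_in >= 0,
            thin >= 1)
  structure(list(include_mid_age = include_mid_age, prior_sd = prior_sd,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 log_effort = log_effort, min_detections = min_detections,
                 enforce_min_detections = enforce_min_detections,
                 seed = as.integer(seed)),
            class = "occu_model_spec")
}

split_rhat <- function(chains) {
  # chains: iterations x chains matrix for one coefficient
  n <- nrow(chains)
  half <- n %/% 2
  segs <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[(n - half + 1):n, j])
  }))
  m <- ncol(segs)
  nn <- nrow(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_geyer <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(0)
  rho <- stats::acf(x, lag.max = min(n - 2, 400), plot = FALSE)$acf[-1]
  # Geyer initial positive sequence on paired sums
  pairs <- rho[seq(1, length(rho) - 1, by = 2)] + rho[seq(2, length(rho), by = 2)]
  keep <- which(pairs <= 0)
  cut <- if (length(keep)) 2 * (keep[1] - 1) else length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(cut)])
  max(1, n / max(tau, 1))
}

#' Fit the occupancy model by adaptive MCMC
#'
#' Samples the joint posterior of the six coefficients under independent
#' Normal(0, `prior_sd`) priors, using adaptive Metropolis-within-Gibbs on
#' the exactly marginalized likelihood (no latent-state augmentation). Effort
#' is standardized (mean 0, SD 1) before fitting. Convergence is assessed by
#' split-R-hat and effective sample size per coefficient; a fit with any
#' split-R-hat above 1.1 is flagged `converged = FALSE` (loudly, via a
#' warning) but still returned for inspection.
#'
#' @param detections Detection table (see [occu_loglik()]).
#' @param spec An [occu_model_spec()].
#' @param fixed Optional named list of coefficients to hold fixed (not
#'   sampled), e.g. `list(alpha0 = 20, alpha1 = 0)` forces occupancy to ~1
#'   and reduces the model to logistic regression on detections.
#' @return An object of class `"occu_fit"`: `draws` (combined post-burn-in
#'   matrix), `summary` (per-coefficient mean, sd, 2.5/97.5% quantiles,
#'   split-R-hat, ESS), `converged`, `warnings`, `spec`, `effort_scaling`.
#' @export
fit_occupancy_mcmc <- function(detections, spec = occu_model_spec(),
                               fixed = NULL) {
  stopifnot(inherits(spec, "occu_model_spec"))
  if (!spec$include_mid_age) {
    detections <- detections[detections$age_class != "mid", , drop = FALSE]
  }
  if (nrow(detections) == 0) stop("no visits left after age filtering")
  d <- occu_prepare(detections, standardize_effort = TRUE,
                    log_effort = spec$log_effort)
  warns <- character(0)
  if (d$n_detections < spec$min_detections) {
    msg <- sprintf("only %d detection records (< %d minimum)",
                   d$n_detections, spec$min_detections)
    if (spec$enforce_min_detections) stop(msg, "; set enforce_min_detections = FALSE to override")
    warns <- c(warns, msg)
  }
  coefs <- c("alpha0", "alpha1", "beta0", "beta1", "beta2", "beta3")
  init <- setNames(numeric(6), coefs)
  fixed_mask <- setNames(rep(FALSE, 6), coefs)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), coefs)
    if (length(bad)) stop("unknown fixed coefficients: ", paste(bad, collapse = ", "))
    init[names(fixed)] <- unlist(fixed)
    fixed_mask[names(fixed)] <- TRUE
  }
  keep_idx <- seq(spec$burn_in + 1L, spec$n_iter, by = spec$thin)
  chains <- vector("list", spec$n_chains)
  for (c in seq_len(spec$n_chains)) {
    set.seed(spec$seed + c - 1L)
    dr <- occu_mcmc_chain_cpp(d$square0, d$y, d$effort, d$over50, d$male,
                              d$first_atlas, spec$n_iter, init,
                              spec$prior_sd, fixed_mask, 0.2,
                              spec$burn_in)
    colnames(dr) <- coefs
    chains[[c]] <- dr[keep_idx, , drop = FALSE]
  }
  draws <- do.call(rbind, chains)
  free <- coefs[!fixed_mask]
  rhat <- setNames(rep(NA_real_, 6), coefs)
  ess <- setNames(rep(NA_real_, 6), coefs)
  for (j in free) {
    mat <- do.call(cbind, lapply(chains, function(ch) ch[, j]))
    rhat[j] <- if (spec$n_chains > 1) split_rhat(mat) else 1
    ess[j] <- sum(apply(mat, 2, ess_geyer))
  }
  converged <- all(rhat[free] <= 1.1, na.rm = TRUE)
  if (!converged) {
    warns <- c(warns, paste0("split-R-hat > 1.1 on: ",
                             paste(free[rhat[free] > 1.1], collapse = ", ")))
    warning("occupancy MCMC did not converge (", warns[length(warns)], ")")
  }
  big <- free[abs(colMeans(draws)[free]) > 10]
  if (length(big)) {
    warns <- c(warns,
               paste0("possible complete separation (|posterior mean| > 10): ",
                      paste(big, collapse = ", ")))
    warning(warns[length(warns)])
  }
  summ <- data.frame(
    coefficient = coefs,
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = apply(draws, 2, quantile, 0.025),
    q97.5 = apply(draws, 2, quantile, 0.975),
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(draws = draws, summary = summ, converged = converged,
                 warnings = warns, spec = spec,
                 effort_scaling = d$effort_scaling,
                 n_squares = d$n_squares, n_detections = d$n_detections),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Occupancy/detection model fit (", nrow(x$draws), " retained draws, ",
      x$n_squares, " squares, ", x$n_detections, " detections)\n", sep = "")
  print(x$summary, digits = 3)
  cat(if (x$converged) "Converged (all split-R-hat <= 1.1)\n"
      else "NOT CONVERGED\n")
  invisible(x)
}

#' Extract the observer-age contrast from a fit
#'
#' Reports the posterior mean, 95% credible interval, significance flags and
#' posterior variance of `beta2`. The variance is the inverse-variance weight
#' used by the downstream frequency regressions. A species "declines" when
#' the 95% interval excludes zero on the negative side.
#'
#' @param fit An [`occu_fit`][fit_occupancy_mcmc()] object.
#' @param allow_nonconverged Set `TRUE` to extract from a flagged fit anyway.
#' @return List with `estimate`, `ci` (length 2), `significant` (interval
#'   excludes 0), `significant_negative`, `variance`.
#' @export
extract_beta2 <- function(fit, allow_nonconverged = FALSE) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!fit$converged && !allow_nonconverged) {
    stop("fit did not converge (", paste(fit$warnings, collapse = "; "),
         "); refusing to extract beta2")
  }
  dr <- fit$draws[, "beta2"]
  if (var(dr) <= 0) stop("degenerate beta2 posterior (zero variance)")
  ci <- unname(quantile(dr, c(0.025, 0.975)))
  sig <- ci[1] > 0 || ci[2] < 0
  list(estimate = mean(dr), ci = ci, significant = sig,
       significant_negative = sig && ci[2] < 0, variance = var(dr))
}

#' Age-disparity sensitivity refit
#'
#' Compares the primary age contrast (mid-aged observers excluded) with a
#' refit on data of all ages in which mid-aged (40-50) observers join the
#' "young" class while the age-50 cutoff is retained. When detection declines
#' monotonically with age, diluting the young class with mid-aged observers
#' shrinks the apparent contrast: `|beta2(with)| < |beta2(without)|`.
#'
#' @param data_with_mid Detection table including mid-aged visits.
#' @param data_without_mid Detection table with mid-aged visits removed;
#'   defaults to dropping them from `data_with_mid`. The two tables must
#'   differ only by mid-age visits.
#' @param spec An [occu_model_spec()]; its seed is used for both fits.
#' @return List with `fit_with`, `fit_without`, `beta2_with`, `beta2_without`
#'   (each an [extract_beta2()] result) and `difference`
#'   (`beta2_with$estimate - beta2_without$estimate`).
#' @export
sensitivity_refit <- function(data_with_mid,
                              data_without_mid =
                                data_with_mid[data_with_mid$age_class != "mid", ],
                              spec = occu_model_spec()) {
  non_mid <- data_with_mid[data_with_mid$age_class != "mid", , drop = FALSE]
  if (nrow(non_mid) != nrow(data_without_mid)) {
    stop("`data_without_mid` must equal `data_with_mid` minus mid-age visits")
  }
  spec_with <- spec
  spec_with$include_mid_age <- TRUE
  spec_without <- spec
  spec_without$include_mid_age <- FALSE
  fit_with <- fit_occupancy_mcmc(data_with_mid, spec_with)
  fit_without <- fit_occupancy_mcmc(data_without_mid, spec_without)
  b_with <- extract_beta2(fit_with, allow_nonconverged = TRUE)
  b_without <- extract_beta2(fit_without, allow_nonconverged = TRUE)
  list(fit_with = fit_with, fit_without = fit_without,
       beta2_with = b_with, beta2_without = b_without,
       difference = b_with$estimate - b_without$estimate)
}
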