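# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (enumeration, closed forms) so it cannot share a bug
# with the implementation under test.

# Brute-force marginal likelihood: enumerate the latent occupancy state of
# every square and sum the joint probability.
enum_occu_loglik <- function(params, det) {
  total <- 0
  for (d in split(det, det$square)) {
    psi <- plogis(params[["alpha0"]] + params[["alpha1"]] * d$first_atlas[1])
    p <- plogis(params[["beta0"]] + params[["beta1"]] * d$effort +
                  params[["beta2"]] * (d$age_class == "over50") +
                  params[["beta3"]] * (d$gender == "male"))
    lik <- 0
    for (z in 0:1) {
      pz <- if (z == 1) psi else 1 - psi
      py <- if (z == 1) {
        prod(ifelse(d$detected == 1, p, 1 - p))
      } else {
        as.numeric(all(d$detected == 0))
      }
      lik <- lik + pz * py
    }
    total <- total + log(lik)
  }
  total
}

# Weighted least squares by the normal equations.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

# Pearson r and its exact t-transform two-sided p-value from the sum
# formulas.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(tt, n - 2, lower.tail = FALSE))
}

coefs0 <- c(alpha0 = 0, alpha1 = 0, beta0 = 0, beta1 = 0, beta2 = 0,
            beta3 = 0)

# Random small detection instance for oracle comparisons.
rand_detections <- function(n_squares, n_visits = 3) {
  n <- n_squares * n_visits
  data.frame(
    square = rep(seq_len(n_squares), each = n_visits),
    year = rep(seq_len(n_visits), n_squares),
    observer = "x",
    age_class = sample(c("under40", "over50"), n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE),
    effort = runif(n, 0.5, 2),
    species = "S",
    detected = rbinom(n, 1, 0.5),
    first_atlas = rep(rbinom(n_squares, 1, 0.5), each = n_visits),
    stringsAsFactors = FALSE
  )
}

# Hand-built power spectrum object (for unit tests that bypass the FFT).
make_spectrum <- function(freqs, power) {
  structure(list(frequencies = freqs, power = power,
                 params = list(fft_size = NA, overlap = NA, rate = NA)),
            class = "power_spectrum")
}

# Hand-built occupancy fit carrying prescribed beta2 draws (for testing
# extract_beta2's decision rules in isolation).
fake_occu_fit <- function(beta2_draws, converged = TRUE) {
  draws <- matrix(0, nrow = length(beta2_draws), ncol = 6,
                  dimnames = list(NULL, c("alpha0", "alpha1", "beta0",
                                          "beta1", "beta2", "beta3")))
  draws[, "beta2"] <- beta2_draws
  structure(list(draws = draws, converged = converged,
                 warnings = character(0)),
            class = "occu_fit")
}

# BBS world used by the GAMM recovery and null checks: no population trend,
# no observer heterogeneity, optional log-linear decline to 50% by age 39.
bbs_recovery_config <- function(seed, decline = TRUE,
                                overdispersion = 1) {
  bbs_sim_config(
    n_strata = 4, routes_per_stratum = 6, years = 1970:2007,
    tenure_dist = function(n) pmin(39L, 10L + as.integer(stats::rgeom(n, 1 / 15))),
    baseline_log_mean = function(n) rep(log(10), n),
    stratum_trend_fn = function(year, stratum) 0,
    age_decline_fn = if (decline) function(age) log(0.5) * (age - 1) / 38
                     else function(age) 0,
    observer_sd = 0, overdispersion = overdispersion,
    history_years = 20, seed = seed)
}

filtered_bbs_records <- function(config) {
  sim <- simulate_bbs(config)
  aged <- compute_min_observer_age(sim$counts, sim$observers)
  apply_filters(aged)$records
}
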