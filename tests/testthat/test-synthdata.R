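test_that("hearing threshold shift follows the quadratic model", {
  expect_equal(hearing_threshold_shift(18, "male", 8), 0)
  coeffs <- data.frame(sex = "female", freq_khz = 4, a = 0.01)
  expect_equal(hearing_threshold_shift(48, "female", 4, coeffs), 0.01 * 30^2)
  # men lose high-frequency hearing faster than women
  expect_gt(hearing_threshold_shift(60, "male", 8),
            hearing_threshold_shift(60, "female", 8))
  expect_error(hearing_threshold_shift(17, "male", 8), "age")
  expect_error(hearing_threshold_shift(30, "male", 5.5), "not a configured")
})

test_that("simulate_atlas honours forced probability regimes", {
  # psi and p pushed to ~1: every record detected
  cfg <- atlas_sim_config(n_squares = 60, years = 2001:2003, alpha0 = 20,
                          alpha1 = 0, beta0 = 20, beta1 = 0, beta2 = 0,
                          beta3 = 0, seed = 1)
  expect_true(all(simulate_atlas(cfg)$detections$detected == 1))
  # saturated negative age contrast: old cohort detects ~nothing
  cfg2 <- atlas_sim_config(n_squares = 300, years = 2001:2004, alpha0 = 20,
                           alpha1 = 0, beta0 = 0, beta1 = 0, beta2 = -20,
                           beta3 = 0, seed = 2)
  det <- simulate_atlas(cfg2)$detections
  old <- det[det$age_class == "over50", ]
  expect_gt(nrow(old), 100)
  expect_equal(sum(old$detected), 0)
})

test_that("null age contrast gives equal cohort detection rates", {
  # binomial-SE oracle: with beta2 = 0 the old/young empirical rates agree
  cfg <- atlas_sim_config(n_squares = 2500, years = 2001:2004, alpha0 = 20,
                          alpha1 = 0, beta0 = 0, beta1 = 0, beta2 = 0,
                          beta3 = 0, seed = 3)
  det <- simulate_atlas(cfg)$detections
  expect_gte(nrow(det), 1e4)
  young <- det$detected[det$age_class == "under40"]
  old <- det$detected[det$age_class == "over50"]
  se <- sqrt(mean(det$detected) * (1 - mean(det$detected)) *
               (1 / length(young) + 1 / length(old)))
  expect_lt(abs(mean(young) - mean(old)), 3 * se)
})

test_that("atlas simulation is seed-deterministic and matches psi * E[p]", {
  a <- simulate_atlas(atlas_sim_config(n_squares = 50, seed = 7))
  b <- simulate_atlas(atlas_sim_config(n_squares = 50, seed = 7))
  expect_identical(a, b)
  # marginal detection rate across replicates equals mean(psi * p)
  rates <- diff <- numeric(20)
  for (r in 1:20) {
    sim <- simulate_atlas(atlas_sim_config(n_squares = 120, years = 2001:2003,
                                           seed = 100 + r))
    d <- sim$detections
    p <- plogis(sim$truth$beta0 + sim$truth$beta1 * d$effort +
                  sim$truth$beta2 * (d$age_class == "over50") +
                  sim$truth$mid_coef * (d$age_class == "mid") +
                  sim$truth$beta3 * (d$gender == "male"))
    expected <- mean(sim$truth$psi[d$square] * p)
    rates[r] <- mean(d$detected)
    diff[r] <- rates[r] - expected
  }
  expect_lt(abs(mean(diff)), 3 * sd(rates) / sqrt(20))
})

test_that("simulate_bbs reproduces its stated moments", {
  # Poisson-SE oracle under the null configuration
  cfg <- bbs_sim_config(n_strata = 4, routes_per_stratum = 5,
                        years = 1990:2009,
                        baseline_log_mean = log(12),
                        stratum_trend_fn = function(y, s) 0,
                        age_decline_fn = function(a) 0,
                        observer_sd = 0, overdispersion = 1,
                        history_years = 0, seed = 5)
  cnt <- simulate_bbs(cfg)$counts$count
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_lt(abs(mean(cnt) - 12), 3 * sqrt(12 / length(cnt)))
  # overdispersion multiplier shows up as the variance/mean ratio
  cfg2 <- bbs_sim_config(n_strata = 10, routes_per_stratum = 12,
                         years = 1980:2009, baseline_log_mean = log(12),
                         stratum_trend_fn = function(y, s) 0,
                         age_decline_fn = function(a) 0, observer_sd = 0,
                         overdispersion = 2.5, history_years = 0, seed = 6)
  cnt2 <- simulate_bbs(cfg2)$counts$count
  expect_lt(abs(var(cnt2) / mean(cnt2) - 2.5), 0.35)
})

test_that("simulate_bbs honours the age-decline construction and edge cases", {
  expect_error(bbs_sim_config(age_decline_fn = function(a) a),
               "must be 0")
  # by construction the expected count ratio age 39 vs 1 is the configured one
  f <- function(age) log(0.5) * (age - 1) / 38
  cfg <- bbs_sim_config(age_decline_fn = f)
  expect_equal(exp(cfg$age_decline_fn(39) - cfg$age_decline_fn(1)), 0.5)
  # degenerate baseline: all counts zero
  cfg0 <- bbs_sim_config(n_strata = 1, routes_per_stratum = 2,
                         years = 1990:1999, baseline_log_mean = -Inf,
                         stratum_trend_fn = function(y, s) 0,
                         age_decline_fn = function(a) 0,
                         observer_sd = 0, history_years = 0, seed = 1)
  expect_true(all(simulate_bbs(cfg0)$counts$count == 0))
  # determinism
  expect_identical(simulate_bbs(bbs_sim_config(seed = 9))$counts,
                   simulate_bbs(bbs_sim_config(seed = 9))$counts)
})

test_that("synthesized vocalizations have the prescribed spectral content", {
  pure <- synthesize_vocalization(
    vocal_spec(components = data.frame(freq_khz = 7, amp = 1,
                                       sweep_to_khz = NA)), seed = 1)
  spec <- compute_power_spectrum(pure)
  bin <- spec$frequencies[2] - spec$frequencies[1]
  expect_lt(abs(peak_frequency(spec) - 7), bin + 1e-9)
  two <- synthesize_vocalization(
    vocal_spec(components = data.frame(freq_khz = c(3, 8), amp = c(1, 0.5),
                                       sweep_to_khz = NA)), seed = 1)
  expect_lt(abs(peak_frequency(compute_power_spectrum(two)) - 3), bin + 1e-9)
  # a 10-tone stack spreads power: larger linear-power SD for the pure tone
  stack <- synthesize_vocalization(
    vocal_spec(components = data.frame(freq_khz = seq(3, 5, length.out = 10),
                                       amp = 1, sweep_to_khz = NA)), seed = 2)
  expect_gt(spectrum_sd(spec), spectrum_sd(compute_power_spectrum(stack)))
  expect_error(vocal_spec(sample_rate = 10000,
                          components = data.frame(freq_khz = 6, amp = 1,
                                                  sweep_to_khz = NA)),
               "Nyquist")
})

test_that("WAV files round-trip waveforms", {
  w <- synthesize_vocalization(vocal_spec(duration = 0.2), seed = 4)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, f)
  r <- read_wav(f)
  expect_equal(r$rate, w$rate)
  expect_equal(length(r$samples), length(w$samples))
  # 16-bit quantization: correlation essentially 1
  expect_gt(cor(r$samples, w$samples), 0.99999)
})
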