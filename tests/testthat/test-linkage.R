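mk_rows <- function(n = 9, het = "monotone", peak = NULL, beta2 = NULL,
                    var = NULL, seed = 1) {
  set.seed(seed)
  peak <- if (is.null(peak)) seq(6.1, 8.9, length.out = n) else peak
  data.frame(species = sprintf("sp%02d", seq_len(n)), peak_khz = peak,
             heterogeneity = het,
             beta2 = if (is.null(beta2)) rnorm(n, -0.5, 0.3) else beta2,
             beta2_var = if (is.null(var)) runif(n, 0.05, 0.2) else var,
             stringsAsFactors = FALSE)
}

test_that("beta2-frequency smooth honours constant and dominant-weight limits", {
  rows <- mk_rows(8, beta2 = rep(-0.5, 8), var = rep(0.1, 8))
  fit <- fit_beta2_vs_frequency(rows, "monotone")
  expect_equal(unname(fit$intercept["estimate"]), -0.5, tolerance = 1e-8)
  expect_lt(max(abs(fit$grid$fit - (-0.5))), 1e-6)
  # a point weighted 1e6x the others pulls the curve through itself
  rows2 <- mk_rows(8, seed = 2)
  rows2$beta2_var[4] <- rows2$beta2_var[4] / 1e6
  fit2 <- fit_beta2_vs_frequency(rows2, "monotone")
  at <- which.min(abs(fit2$grid$peak_khz - rows2$peak_khz[4]))
  expect_lt(abs(fit2$grid$fit[at] - rows2$beta2[4]), 0.05)
  expect_error(fit_beta2_vs_frequency(mk_rows(4), "monotone"), ">= 5")
})

test_that("the linear limit of the smooth equals closed-form WLS", {
  rows <- mk_rows(10, var = rep(0.1, 10), seed = 3)
  fit <- fit_beta2_vs_frequency(rows, "monotone", sp = 1e10)
  ora <- wls_oracle(rows$peak_khz, rows$beta2, rep(1, 10))
  pred_oracle <- ora[1] + ora[2] * fit$grid$peak_khz
  expect_equal(fit$grid$fit, pred_oracle, tolerance = 1e-6)
})

test_that("post-hoc high-frequency linear model matches the WLS oracle", {
  # exact line: slope recovered exactly, p tiny
  rows <- mk_rows(9, peak = seq(6, 9, length.out = 9))
  rows$beta2 <- 1.2 - 0.4 * rows$peak_khz
  rows$beta2_var <- rep(0.1, 9)
  fit <- posthoc_highfreq_linear(rows)
  expect_equal(unname(fit$coefficients["peak_khz"]), -0.4, tolerance = 1e-10)
  expect_lt(fit$p_slope, 1e-6)
  # unequal weights, noisy data: equals normal equations to 1e-10
  rows2 <- mk_rows(9, seed = 4)
  fit2 <- posthoc_highfreq_linear(rows2)
  w <- (1 / rows2$beta2_var) / mean(1 / rows2$beta2_var)
  ora <- wls_oracle(rows2$peak_khz, rows2$beta2, w)
  expect_equal(unname(fit2$coefficients), unname(ora), tolerance = 1e-10)
  # subset rule: only monotone >= 6 kHz enter; zero-weighting the excluded
  # rows in a direct lm gives the same coefficients
  rows3 <- rbind(rows2, mk_rows(4, het = "heterogeneous",
                                peak = c(2, 5, 7, 8), seed = 5))
  rows3 <- rbind(rows3, mk_rows(2, het = "monotone", peak = c(2.5, 5.5),
                                seed = 6))
  rows3$species <- sprintf("sp%02d", seq_len(nrow(rows3)))
  fit3 <- posthoc_highfreq_linear(rows3)
  expect_equal(unname(fit3$coefficients), unname(fit2$coefficients),
               tolerance = 1e-10)
  expect_error(posthoc_highfreq_linear(mk_rows(2)), ">= 3")
})

test_that("null slopes are not over-detected", {
  # type-I check at reduced replicates: slope-0 truth, alpha = 0.05
  hits <- 0
  for (r in 1:200) {
    rows <- mk_rows(9, beta2 = rnorm(9, -0.5, 0.3), var = runif(9, 0.05, 0.2),
                    seed = 1000 + r)
    if (posthoc_highfreq_linear(rows)$p_slope < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 20)
})

test_that("trend-frequency smooths respect weights and structure", {
  rows <- mk_rows(12, peak = seq(3, 9, length.out = 12), seed = 7)
  rows$trend_a <- ifelse(rows$peak_khz >= 6, -2, 0) # step down above 6 kHz
  rows$trend_a_ci_width <- runif(12, 0.5, 2)
  fit <- fit_trend_vs_frequency(rows, "a", "monotone")
  lo <- mean(fit$grid$fit[fit$grid$peak_khz < 6])
  hi <- mean(fit$grid$fit[fit$grid$peak_khz >= 6])
  expect_gt(lo, hi)
  # doubling the route-count weights changes nothing
  rows$trend_b <- rows$trend_a
  rows$trend_b_n_routes <- round(runif(12, 10, 100))
  f1 <- fit_trend_vs_frequency(rows, "b", "monotone")
  rows2 <- rows; rows2$trend_b_n_routes <- rows2$trend_b_n_routes * 2
  f2 <- fit_trend_vs_frequency(rows2, "b", "monotone")
  expect_equal(f1$grid$fit, f2$grid$fit, tolerance = 1e-8)
  rows3 <- rows; rows3$trend_a_ci_width[1] <- -1
  expect_error(fit_trend_vs_frequency(rows3, "a", "monotone"), "positive")
})

test_that("constant trends yield non-significant smooths", {
  hits <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    rows <- mk_rows(12, seed = 300 + r)
    rows$trend_a <- rnorm(12, -1, 0.4) # no frequency structure
    rows$trend_a_ci_width <- runif(12, 0.5, 2)
    fit <- fit_trend_vs_frequency(rows, "a", "monotone")
    if (fit$smooth_p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)
})

test_that("Pearson correlation matches the closed form and flags influence", {
  rows <- mk_rows(9)
  rows$trend_a <- 2 + 3 * rows$beta2 # exact line
  co <- correlate_beta2_trend(rows, "a")
  expect_equal(co$r, 1, tolerance = 1e-10)
  # 3-point hand example, frozen from the sum-formula oracle
  ora <- pearson_oracle(c(0, 1, 2), c(0, 1, 4))
  expect_equal(ora$r, sqrt(16 / (2 * 78 / 9)), tolerance = 1e-12)
  rows3 <- mk_rows(3, peak = c(6.5, 7, 8), beta2 = c(0, 1, 2), var = rep(0.1, 3))
  rows3$trend_a <- c(0, 1, 4)
  co3 <- correlate_beta2_trend(rows3, "a")
  expect_equal(co3$r, 0.9607689, tolerance = 1e-6)
  expect_equal(co3$p, ora$p, tolerance = 1e-10)
  # exact p-transform property on random instances
  for (s in 1:5) {
    rows_r <- mk_rows(8, seed = 400 + s)
    rows_r$trend_a <- rnorm(8)
    co_r <- correlate_beta2_trend(rows_r, "a")
    ora_r <- pearson_oracle(rows_r$beta2, rows_r$trend_a)
    expect_equal(co_r$r, ora_r$r, tolerance = 1e-10)
    expect_equal(co_r$p, ora_r$p, tolerance = 1e-10)
  }
  # zero variance refuses
  rows0 <- mk_rows(5)
  rows0$trend_a <- 1
  expect_error(correlate_beta2_trend(rows0, "a"), "variance")
})

test_that("leave-one-out exposes a single engineered influential point", {
  set.seed(17)
  n <- 8
  rows <- mk_rows(n, peak = seq(6.2, 8.4, length.out = n))
  rows$beta2 <- rnorm(n, 0, 0.25)
  rows$trend_a <- rnorm(n, 0, 0.25)
  # one high-leverage point manufactures the correlation
  rows$beta2[n] <- -3; rows$trend_a[n] <- -6
  co <- correlate_beta2_trend(rows, "a")
  expect_lt(co$p, 0.05)
  flip <- co$loo$p >= 0.05
  expect_true(flip[co$loo$species_removed == rows$species[n]])
  expect_equal(sum(flip), 1)
})
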