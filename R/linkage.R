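#' Species-effect join table
#'
#' The linkage analyses operate on one row per species joining the
#' vocalization classification, the occupancy-model age contrast, and two
#' externally published per-year population trends:
#' `species`, `peak_khz`, `heterogeneity` ("monotone"/"heterogeneous"),
#' `beta2` (posterior mean), `beta2_var` (posterior variance, the
#' inverse-variance weight), `trend_a` + `trend_a_ci_width` (trend source A,
#' weighted by inverse 95%-interval width), `trend_b` + `trend_b_n_routes`
#' (trend source B, weighted by route count).
#'
#' @param rows A data.frame; checked for the required columns.
#' @param need Character vector of additionally required columns.
#' @return `rows`, invisibly, after validation.
#' @keywords internal
check_effect_rows <- function(rows, need = character(0)) {
  req <- c("species", "peak_khz", "heterogeneity", need)
  miss <- setdiff(req, names(rows))
  if (length(miss)) stop("rows missing columns: ", paste(miss, collapse = ", "))
  if ("beta2_var" %in% need && any(rows$beta2_var <= 0)) {
    stop("beta2_var must be strictly positive (posterior variances)")
  }
  invisible(rows)
}

norm_weights <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be finite and positive")
  w / mean(w) # mean-1 normalization for numerical stability; fits are scale-invariant
}

#' Weighted spline fit of the age contrast on vocalization frequency
#'
#' Penalized thin-plate spline regression of the per-species detection
#' contrast `beta2` on peak vocalization frequency, fitted separately for the
#' monotone and heterogeneous species and weighted by the inverse posterior
#' variance of each `beta2`. The model intercept estimates the central
#' tendency of the contrasts (a significantly negative intercept means
#' detection declines with observer age across the board).
#'
#' @param rows Species-effect table (see [check_effect_rows()]); needs
#'   `beta2`, `beta2_var`.
#' @param subset `"monotone"` or `"heterogeneous"`.
#' @param k Spline basis dimension (shrunk with a message when there are
#'   fewer points).
#' @param ... Passed to [mgcv::gam()] (e.g. `sp` to force the linear limit).
#' @return A `"weighted_fit"`: mgcv model, evaluation `grid`
#'   (`peak_khz`, `fit`, `se`), `intercept` (estimate, se, p), `smooth_p`,
#'   `n`, `weights`.
#' @export
fit_beta2_vs_frequency <- function(rows, subset = c("monotone", "heterogeneous"),
                                   k = 10, ...) {
  subset <- match.arg(subset)
  check_effect_rows(rows, c("beta2", "beta2_var"))
  d <- rows[rows$heterogeneity == subset, , drop = FALSE]
  if (nrow(d) < 5) stop("need >= 5 species in the ", subset, " subset")
  w <- norm_weights(1 / d$beta2_var)
  weighted_smooth(d$peak_khz, d$beta2, w, k, ...)
}

#' Weighted spline fit of population trend on vocalization frequency
#'
#' Like [fit_beta2_vs_frequency()] but for an externally supplied per-year
#' population trend. Source `"a"` weights by inverse 95%-interval width,
#' source `"b"` by the number of routes behind each trend; weights are
#' normalized to mean 1.
#'
#' @inheritParams fit_beta2_vs_frequency
#' @param trend_source `"a"` or `"b"`.
#' @return A `"weighted_fit"`.
#' @export
fit_trend_vs_frequency <- function(rows, trend_source = c("a", "b"),
                                   subset = c("monotone", "heterogeneous"),
                                   k = 10, ...) {
  trend_source <- match.arg(trend_source)
  subset <- match.arg(subset)
  if (trend_source == "a") {
    check_effect_rows(rows, c("trend_a", "trend_a_ci_width"))
    d <- rows[rows$heterogeneity == subset, , drop = FALSE]
    d <- d[complete.cases(d[, c("trend_a", "trend_a_ci_width")]), , drop = FALSE]
    y <- d$trend_a
    w <- 1 / d$trend_a_ci_width
  } else {
    check_effect_rows(rows, c("trend_b", "trend_b_n_routes"))
    d <- rows[rows$heterogeneity == subset, , drop = FALSE]
    d <- d[complete.cases(d[, c("trend_b", "trend_b_n_routes")]), , drop = FALSE]
    y <- d$trend_b
    w <- d$trend_b_n_routes
  }
  if (nrow(d) < 5) stop("need >= 5 species in the ", subset, " subset")
  weighted_smooth(d$peak_khz, y, norm_weights(w), k, ...)
}

weighted_smooth <- function(x, y, w, k, ...) {
  kk <- min(k, length(x) - 1L)
  if (kk < k) message("basis dimension shrunk to ", kk, " (n = ", length(x), ")")
  d <- data.frame(x = x, y = y)
  m <- tryCatch(
    mgcv::gam(y ~ s(x, k = kk, bs = "tp"), weights = w, data = d,
              method = "REML", ...),
    error = function(e) {
      # REML smoothness selection can fail on degenerate responses (e.g.
      # zero residual variance); fall back to the heavily penalized linear
      # limit, which is exact in those cases
      mgcv::gam(y ~ s(x, k = kk, bs = "tp"), weights = w, data = d,
                sp = 1e10)
    })
  sm <- summary(m)
  grid_x <- seq(min(x), max(x), length.out = 100)
  pr <- predict(m, newdata = data.frame(x = grid_x), se.fit = TRUE)
  structure(list(model = m,
                 grid = data.frame(peak_khz = grid_x, fit = as.numeric(pr$fit),
                                   se = as.numeric(pr$se.fit)),
                 intercept = c(estimate = unname(sm$p.table[1, 1]),
                               se = unname(sm$p.table[1, 2]),
                               p = unname(sm$p.table[1, 4])),
                 smooth_p = unname(sm$s.table[1, "p-value"]),
                 n = length(x), weights = w),
            class = "weighted_fit")
}

#' Post-hoc weighted linear model for high-frequency monotone species
#'
#' Inverse-variance-weighted simple linear regression of `beta2` on peak
#' frequency, restricted to species with monotone vocalizations at or above
#' `min_freq` kHz (default 6, the medium/high threshold). A significantly
#' negative slope means detection losses worsen with song pitch — the
#' hearing-loss signature.
#'
#' @param rows Species-effect table with `beta2`, `beta2_var`.
#' @param min_freq Frequency cutoff in kHz.
#' @return A `"wls_fit"`: `coefficients` (intercept, slope), `se`,
#'   `p_slope` (two-sided), `n`, `model`, `weights`.
#' @export
posthoc_highfreq_linear <- function(rows, min_freq = 6) {
  check_effect_rows(rows, c("beta2", "beta2_var"))
  d <- rows[rows$heterogeneity == "monotone" & rows$peak_khz >= min_freq, ,
            drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 monotone species at >= ", min_freq,
                        " kHz (got ", nrow(d), ")")
  w <- norm_weights(1 / d$beta2_var)
  m <- lm(beta2 ~ peak_khz, data = d, weights = w)
  sm <- summary(m)
  structure(list(coefficients = coef(m),
                 se = sm$coefficients[, 2],
                 p_slope = sm$coefficients["peak_khz", 4],
                 n = nrow(d), model = m, weights = w),
            class = "wls_fit")
}

#' Pearson correlation of detection declines with published trends
#'
#' Unweighted Pearson correlation between the `beta2` detection contrasts
#' and a published population trend, over the monotone species at or above
#' `min_freq` kHz, with the exact t-transform two-sided p-value, plus a
#' leave-one-out table showing (r, p) with each species removed (the
#' influential-outlier sensitivity check).
#'
#' @param rows Species-effect table.
#' @param trend_source `"a"` or `"b"`.
#' @param min_freq Frequency cutoff in kHz (default 6).
#' @return List with `r`, `p`, `n` and `loo` (data.frame `species_removed`,
#'   `r`, `p`).
#' @export
correlate_beta2_trend <- function(rows, trend_source = c("a", "b"),
                                  min_freq = 6) {
  trend_source <- match.arg(trend_source)
  tcol <- if (trend_source == "a") "trend_a" else "trend_b"
  check_effect_rows(rows, c("beta2", tcol))
  d <- rows[rows$heterogeneity == "monotone" & rows$peak_khz >= min_freq, ,
            drop = FALSE]
  d <- d[complete.cases(d[, c("beta2", tcol)]), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 species (got ", nrow(d), ")")
  pearson <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
    ct <- cor.test(x, y, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  full <- pearson(d$beta2, d[[tcol]])
  loo <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    if (nrow(d) - 1 < 3) return(NULL)
    v <- pearson(d$beta2[-i], d[[tcol]][-i])
    data.frame(species_removed = d$species[i], r = v["r"], p = v["p"],
               row.names = NULL)
  }))
  list(r = unname(full["r"]), p = unname(full["p"]), n = nrow(d), loo = loo)
}
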