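#' Built-in age-related hearing threshold shift coefficients
#'
#' Quadratic coefficients `a` (dB per squared year past age 18) for the median
#' expected hearing threshold shift at the standard pure-tone audiometric test
#' frequencies 1, 4, 6 and 8 kHz, by sex. The shift at `age` is
#' `a * (age - 18)^2`. The values are approximate, synthetic stand-ins chosen
#' to reproduce the qualitative structure of the international audiometric
#' standard: shifts grow with frequency and men lose high-frequency hearing
#' faster than women. Override them via the `coeffs` argument of
#' [hearing_threshold_shift()] when calibrated constants are available.
#'
#' @return A data.frame with columns `sex`, `freq_khz`, `a`.
#' @export
default_hearing_coeffs <- function() {
  data.frame(
    sex      = rep(c("male", "female"), each = 4),
    freq_khz = rep(c(1, 4, 6, 8), 2),
    a        = c(0.004, 0.016, 0.018, 0.022,   # male
                 0.004, 0.009, 0.012, 0.015),  # female
    stringsAsFactors = FALSE
  )
}

#' Median age-related hearing threshold shift
#'
#' Returns the expected shift in the pure-tone hearing threshold (dB, relative
#' to age 18) for an observer of a given age and sex at one of the configured
#' test frequencies, using a quadratic-in-age model `a * (age - 18)^2`. In
#' this package the shift is used only to parameterize the age effects of the
#' survey simulators (e.g. mapping a dB loss at a species' song frequency into
#' a logit-scale detection contrast).
#'
#' @param age Observer age in years, `>= 18`.
#' @param sex `"male"` or `"female"`.
#' @param freq Test frequency in kHz; must be one of the configured
#'   frequencies in `coeffs`.
#' @param coeffs Coefficient table as returned by [default_hearing_coeffs()].
#' @return Threshold shift in dB (0 at age 18).
#' @examples
#' hearing_threshold_shift(60, "male", 8)
#' @export
hearing_threshold_shift <- function(age, sex, freq,
                                    coeffs = default_hearing_coeffs()) {
  if (!is.numeric(age) || any(age < 18)) {
    stop("`age` must be >= 18 (shift model is anchored at age 18)")
  }
  sex <- match.arg(sex, c("male", "female"))
  row <- coeffs[coeffs$sex == sex & coeffs$freq_khz == freq, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("frequency ", freq, " kHz is not a configured test frequency (",
         paste(sort(unique(coeffs$freq_khz)), collapse = ", "), " kHz)")
  }
  row$a * (age - 18)^2
}

#' Configuration for the atlas detection simulator
#'
#' Defines the data-generating world for [simulate_atlas()]: a set of atlas
#' squares, each with a latent occupancy state driven by a first-atlas
#' detection flag, surveyed in replicate years by observers drawn from three
#' age cohorts, with logistic detection depending on effort, an over-50 age
#' indicator, and gender.
#'
#' Occupancy: `logit(psi_i) = alpha0 + alpha1 * firstAtlas_i`.
#' Detection: `logit(p_ik) = beta0 + beta1 * effort_ik +
#'   beta2 * I(over50_ik) + beta3 * I(male_ik)`.
#'
#' Defaults encode the stated survey world: 400 squares over a 5-year atlas
#' period, an age contrast `beta2 = -0.66` (negative: older observers detect
#' less) and a small positive male effect `beta3 = 0.17`; effort is log-normal
#' (strictly positive party-hours, centred near the 20 party-hour survey
#' minimum).
#'
#' @param n_squares Number of atlas squares.
#' @param years Vector of survey years (replicate visits per square).
#' @param alpha0,alpha1 Occupancy intercept and first-atlas coefficient
#'   (logit scale).
#' @param beta0 Detection intercept (logit scale).
#' @param beta1 Detection effort coefficient (logit per party-hour).
#' @param beta2 Old-vs-young detection contrast (logit scale).
#' @param mid_coef Mid-cohort (40-50) detection contrast relative to the
#'   young cohort (logit scale). 0 (default) makes mid-aged observers detect
#'   like young ones; set to an intermediate value (e.g. `beta2 / 2`) for a
#'   monotone age-declining world, the regime the sensitivity refit probes.
#' @param beta3 Male-vs-female detection contrast (logit scale).
#' @param cohort_mix Named proportions for the `under40` / `mid` / `over50`
#'   observer cohorts; must sum to 1.
#' @param effort_dist `c(meanlog, sdlog)` of the log-normal effort draw
#'   (party-hours, strictly positive).
#' @param n_observers Size of the observer pool.
#' @param p_male Probability an observer is male (survey pools are
#'   male-skewed).
#' @param species Species label written into the detection table.
#' @param seed Integer seed; the simulator is fully reproducible.
#' @return A validated list of class `"atlas_sim_config"`.
#' @export
atlas_sim_config <- function(n_squares = 400,
                             years = 2001:2005,
                             alpha0 = 0.5, alpha1 = 1.0,
                             beta0 = 0.0, beta1 = 0.02,
                             beta2 = -0.66, mid_coef = 0, beta3 = 0.17,
                             cohort_mix = c(under40 = 0.25, mid = 0.35,
                                            over50 = 0.40),
                             effort_dist = c(meanlog = log(30), sdlog = 0.5),
                             n_observers = 300,
                             p_male = 0.7,
                             species = "SP1",
                             seed = 1L) {
  stopifnot(length(n_squares) == 1L, n_squares >= 1, n_squares == round(n_squares),
            length(years) >= 1L, n_observers >= 3L,
            length(effort_dist) == 2L, effort_dist[2] >= 0,
            p_male >= 0, p_male <= 1)
  for (nm in c("alpha0", "alpha1", "beta0", "beta1", "beta2", "mid_coef",
               "beta3")) {
    if (!is.finite(get(nm))) stop("coefficient `", nm, "` must be finite")
  }
  if (length(cohort_mix) != 3L || any(cohort_mix < 0) ||
      abs(sum(cohort_mix) - 1) > 1e-8) {
    stop("`cohort_mix` must be 3 nonnegative proportions summing to 1")
  }
  names(cohort_mix) <- c("under40", "mid", "over50")
  mean_effort <- exp(effort_dist[1] + effort_dist[2]^2 / 2)
  p_mean <- plogis(beta0 + beta1 * mean_effort)
  psi_mean <- plogis(alpha0 + 0.5 * alpha1)
  if (p_mean <= 0 || p_mean >= 1 || psi_mean <= 0 || psi_mean >= 1) {
    stop("implied mean-covariate probabilities are degenerate (0 or 1); ",
         "check alpha0/alpha1/beta0/beta1 against the effort scale")
  }
  structure(list(n_squares = as.integer(n_squares), years = as.integer(years),
                 alpha0 = alpha0, alpha1 = alpha1, beta0 = beta0,
                 beta1 = beta1, beta2 = beta2, mid_coef = mid_coef,
                 beta3 = beta3,
                 cohort_mix = cohort_mix, effort_dist = effort_dist,
                 n_observers = as.integer(n_observers), p_male = p_male,
                 species = species, seed = as.integer(seed)),
            class = "atlas_sim_config")
}

#' Simulate atlas-style detection/nondetection data
#'
#' Draws a complete synthetic atlas survey from an [atlas_sim_config()]:
#' a per-square first-atlas flag (Bernoulli 0.5), latent occupancy
#' `z_i ~ Bernoulli(psi_i)`, one observer per square-year with cohort, gender
#' and log-normal effort, and detections `y ~ Bernoulli(z * p)`. The true
#' parameters and latent states are returned so downstream fits can be tested
#' for parameter recovery.
#'
#' @param config An [atlas_sim_config()].
#' @return A list with elements `detections` (data.frame: `square`, `year`,
#'   `observer`, `age_class`, `gender`, `effort`, `species`, `detected`,
#'   `first_atlas`), `observers` (pool with cohort and gender) and `truth`
#'   (coefficients, latent `z`, `psi`).
#' @examples
#' sim <- simulate_atlas(atlas_sim_config(n_squares = 20, seed = 7))
#' head(sim$detections)
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_sim_config"))
  set.seed(config$seed)
  S <- config$n_squares
  yrs <- config$years

  observers <- data.frame(
    observer  = sprintf("obs%03d", seq_len(config$n_observers)),
    age_class = sample(names(config$cohort_mix), config$n_observers,
                       replace = TRUE, prob = config$cohort_mix),
    gender    = ifelse(runif(config$n_observers) < config$p_male,
                       "male", "female"),
    stringsAsFactors = FALSE
  )

  first_atlas <- rbinom(S, 1L, 0.5)
  psi <- plogis(config$alpha0 + config$alpha1 * first_atlas)
  z <- rbinom(S, 1L, psi)

  n <- S * length(yrs)
  square <- rep(seq_len(S), each = length(yrs))
  year <- rep(yrs, times = S)
  idx <- sample.int(config$n_observers, n, replace = TRUE)
  effort <- rlnorm(n, config$effort_dist[1], config$effort_dist[2])
  over50 <- as.integer(observers$age_class[idx] == "over50")
  mid <- as.integer(observers$age_class[idx] == "mid")
  male <- as.integer(observers$gender[idx] == "male")
  p <- plogis(config$beta0 + config$beta1 * effort +
                config$beta2 * over50 + config$mid_coef * mid +
                config$beta3 * male)
  detected <- rbinom(n, 1L, z[square] * p)

  detections <- data.frame(
    square = square, year = year,
    observer = observers$observer[idx],
    age_class = observers$age_class[idx],
    gender = observers$gender[idx],
    effort = effort, species = config$species,
    detected = detected, first_atlas = first_atlas[square],
    stringsAsFactors = FALSE
  )
  list(detections = detections, observers = observers,
       truth = list(alpha0 = config$alpha0, alpha1 = config$alpha1,
                    beta0 = config$beta0, beta1 = config$beta1,
                    beta2 = config$beta2, mid_coef = config$mid_coef,
                    beta3 = config$beta3,
                    psi = psi, z = z))
}

#' Configuration for the BBS-style count simulator
#'
#' Defines the generating model for [simulate_bbs()]: routes nested in
#' physiographic strata, each route surveyed once per year by a sequence of
#' observers holding multi-year tenures, with log-scale Poisson means
#' `log mu = baseline_route + trend(year, stratum) + u_observer +
#' age_decline(observer_age)` and optional overdispersion.
#'
#' The default `age_decline_fn` is a smooth log-scale decline reaching 50% of
#' the first-year count by observer age 39 (the middle of the range of group
#' declines the analyses are designed to detect); it is 0 at age 1 by
#' construction, making the first year of service the reference.
#'
#' @param n_strata Number of strata.
#' @param routes_per_stratum Routes per stratum.
#' @param years Survey years (calendar).
#' @param tenure_dist Function `n -> n` positive integer tenure lengths.
#' @param baseline_log_mean Function `n -> n` route baselines (log scale), or
#'   a single number recycled to all routes.
#' @param stratum_trend_fn Function `(year, stratum) -> ` log-scale population
#'   effect (vectorized in `year`).
#' @param age_decline_fn Function of minimum observer age (years since first
#'   service, first year = 1) giving the log-scale detection effect; must be
#'   0 at age 1.
#' @param observer_sd SD of observer random intercepts (log scale).
#' @param overdispersion Variance/mean ratio of counts, `>= 1`; implemented as
#'   gamma-distributed mean-1 multiplicative noise on the Poisson mean
#'   (negative-binomial counts) so that `Var(Y) = overdispersion * E(Y)`.
#' @param history_years Years of route history simulated before `years`:
#'   observer tenures are laid down starting this many years early, so first
#'   service years can precede the analysis window (as in the real survey,
#'   where ages are computed from the complete record). This decorrelates
#'   observer age from calendar year across routes. Set 0 to start all
#'   tenures at the window start.
#' @param species Species label.
#' @param seed Integer seed.
#' @return A validated list of class `"bbs_sim_config"`.
#' @export
bbs_sim_config <- function(n_strata = 6,
                           routes_per_stratum = 8,
                           years = 1970:2007,
                           tenure_dist = function(n) pmin(39L, 1L + stats::rgeom(n, 1 / 12)),
                           baseline_log_mean = function(n) rnorm(n, log(10), 0.5),
                           stratum_trend_fn = function(year, stratum) -0.01 * (year - 1970),
                           age_decline_fn = function(age) log(1 - 0.5 * (age - 1) / 38),
                           observer_sd = 0.3,
                           overdispersion = 1.5,
                           history_years = 15,
                           species = "SP1",
                           seed = 1L) {
  stopifnot(n_strata >= 1, routes_per_stratum >= 1, length(years) >= 2L,
            is.function(tenure_dist), is.function(stratum_trend_fn),
            is.function(age_decline_fn), observer_sd >= 0,
            history_years >= 0)
  if (overdispersion < 1) stop("`overdispersion` must be >= 1")
  if (is.numeric(baseline_log_mean)) {
    b <- baseline_log_mean[1]
    baseline_log_mean <- function(n) rep(b, n)
  }
  if (abs(age_decline_fn(1)) > 1e-12) {
    stop("`age_decline_fn(1)` must be 0: the first year of service is the baseline")
  }
  structure(list(n_strata = as.integer(n_strata),
                 routes_per_stratum = as.integer(routes_per_stratum),
                 years = as.integer(years), tenure_dist = tenure_dist,
                 baseline_log_mean = baseline_log_mean,
                 stratum_trend_fn = stratum_trend_fn,
                 age_decline_fn = age_decline_fn,
                 observer_sd = observer_sd, overdispersion = overdispersion,
                 history_years = as.integer(history_years),
                 species = species, seed = as.integer(seed)),
            class = "bbs_sim_config")
}

#' Simulate BBS-style single-visit annual counts
#'
#' Generates one species' worth of route-level annual counts under a
#' [bbs_sim_config()]. Each route is covered by consecutive observer tenures;
#' each observer's first service year is recorded so that minimum observer age
#' can be recomputed downstream exactly as for real data. Counts are Poisson
#' with a multiplicative gamma overdispersion adjustment (`Var = phi * mean`).
#'
#' @param config A [bbs_sim_config()].
#' @return A list with `counts` (data.frame: `stratum`, `route`, `year`,
#'   `observer`, `species`, `count`, `single_observer`, `acceptable_weather`),
#'   `observers` (data.frame: `observer`, `first_service_year`) and `truth`
#'   (generating functions and route baselines).
#' @examples
#' sim <- simulate_bbs(bbs_sim_config(n_strata = 2, routes_per_stratum = 2,
#'                                    years = 1990:1999, seed = 3))
#' head(sim$counts)
#' @export
simulate_bbs <- function(config) {
  stopifnot(inherits(config, "bbs_sim_config"))
  set.seed(config$seed)
  yrs <- config$years
  n_routes <- config$n_strata * config$routes_per_stratum
  baselines <- config$baseline_log_mean(n_routes)

  rows <- vector("list", n_routes)
  obs_first <- list()
  obs_counter <- 0L
  route_id <- 0L
  for (s in seq_len(config$n_strata)) {
    for (r in seq_len(config$routes_per_stratum)) {
      route_id <- route_id + 1L
      # consecutive observer tenures laid down from history_years before the
      # window; only window years yield count records, but first service
      # years (and hence ages) reflect the full tenure history
      ext <- (min(yrs) - config$history_years):max(yrs)
      pos <- 1L
      obs_ext <- integer(length(ext))
      first_ext <- integer(length(ext))
      while (pos <= length(ext)) {
        len <- max(1L, as.integer(config$tenure_dist(1L)))
        obs_counter <- obs_counter + 1L
        span <- pos:min(length(ext), pos + len - 1L)
        obs_ext[span] <- obs_counter
        first_ext[span] <- ext[pos]
        pos <- pos + len
      }
      in_win <- ext %in% yrs
      obs_vec <- obs_ext[in_win]
      first_vec <- first_ext[in_win]
      for (oid in unique(obs_vec)) {
        obs_first[[sprintf("obs%05d", oid)]] <- first_vec[match(oid, obs_vec)]
      }
      u <- rnorm(length(unique(obs_vec)), 0, config$observer_sd)
      names(u) <- as.character(unique(obs_vec))
      age <- yrs - first_vec + 1L
      log_mu <- baselines[route_id] +
        config$stratum_trend_fn(yrs, s) +
        u[as.character(obs_vec)] +
        config$age_decline_fn(age)
      mu <- exp(log_mu)
      if (config$overdispersion > 1) {
        shp <- mu / (config$overdispersion - 1)
        g <- ifelse(mu > 0, rgamma(length(mu), shape = shp, rate = shp), 1)
        mu <- mu * g
      }
      rows[[route_id]] <- data.frame(
        stratum = sprintf("S%02d", s),
        route = sprintf("R%03d", route_id),
        year = yrs,
        observer = sprintf("obs%05d", obs_vec),
        species = config$species,
        count = rpois(length(mu), mu),
        single_observer = TRUE,
        acceptable_weather = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  observers <- data.frame(observer = names(obs_first),
                          first_service_year = as.integer(unlist(obs_first)),
                          stringsAsFactors = FALSE)
  list(counts = counts, observers = observers,
       truth = list(baselines = baselines,
                    stratum_trend_fn = config$stratum_trend_fn,
                    age_decline_fn = config$age_decline_fn,
                    observer_sd = config$observer_sd,
                    overdispersion = config$overdispersion))
}

#' Specification of a synthetic vocalization
#'
#' Describes a stack of (optionally frequency-swept) sinusoids plus a white
#' noise floor, used by [synthesize_vocalization()] as a stand-in for field
#' recordings of birdsong.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @param components Data.frame (or list coercible to one) with columns
#'   `freq_khz`, `amp` and optional `sweep_to_khz` (NA for a steady tone).
#' @param noise_floor White-noise SD relative to component amplitudes.
#' @return A validated list of class `"vocal_spec"`.
#' @export
vocal_spec <- function(sample_rate = 44100, duration = 1.0,
                       components = data.frame(freq_khz = 4, amp = 1,
                                               sweep_to_khz = NA_real_),
                       noise_floor = 0.001) {
  components <- as.data.frame(components)
  if (is.null(components$sweep_to_khz)) components$sweep_to_khz <- NA_real_
  stopifnot(sample_rate > 0, duration > 0, nrow(components) >= 1L,
            all(components$amp >= 0), any(components$amp > 0),
            noise_floor >= 0)
  nyq <- sample_rate / 2 / 1000
  fmax <- pmax(components$freq_khz,
               ifelse(is.na(components$sweep_to_khz), 0,
                      components$sweep_to_khz))
  if (any(fmax >= nyq)) {
    stop("component frequency at or above Nyquist (", nyq, " kHz)")
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 components = components, noise_floor = noise_floor),
            class = "vocal_spec")
}

#' Synthesize a vocal waveform
#'
#' Renders a [vocal_spec()] as a waveform: each component contributes
#' `amp * sin(phase(t))`, with a linear chirp when `sweep_to_khz` is set, plus
#' Gaussian white noise at `noise_floor`. A pure tone's spectral peak falls at
#' its frequency (within one analysis bin).
#'
#' @param spec A [vocal_spec()].
#' @param seed Integer seed for the noise draw.
#' @return A list with `samples` (numeric vector) and `rate` (Hz), class
#'   `"waveform"`.
#' @examples
#' w <- synthesize_vocalization(vocal_spec(components = data.frame(
#'   freq_khz = 7, amp = 1, sweep_to_khz = NA)), seed = 1)
#' @export
synthesize_vocalization <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "vocal_spec"))
  set.seed(seed)
  n <- round(spec$sample_rate * spec$duration)
  t <- (seq_len(n) - 1) / spec$sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(spec$components))) {
    f0 <- spec$components$freq_khz[i] * 1000
    f1 <- spec$components$sweep_to_khz[i] * 1000
    amp <- spec$components$amp[i]
    if (is.na(f1)) {
      x <- x + amp * sin(2 * pi * f0 * t)
    } else {
      # linear chirp f0 -> f1 over the duration
      k <- (f1 - f0) / spec$duration
      x <- x + amp * sin(2 * pi * (f0 * t + k * t^2 / 2))
    }
  }
  if (spec$noise_floor > 0) x <- x + rnorm(n, 0, spec$noise_floor)
  structure(list(samples = x, rate = spec$sample_rate), class = "waveform")
}
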