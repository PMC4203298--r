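#' Zero-fill a count table
#'
#' Raw survey records list only detected species. For every
#' (observer, route, year) survey that is present, this adds an explicit
#' count-0 record for each listed species absent from it, so non-detections
#' enter the models. Survey-level attributes (stratum, weather/observer
#' flags) are copied from the existing records of that survey. The operation
#' is idempotent.
#'
#' @param records Count data.frame with at least `stratum`, `route`, `year`,
#'   `observer`, `species`, `count`.
#' @param species_list Character vector of species to complete to.
#' @return The input plus the added zero rows (attribute `n_added`).
#' @export
zero_fill <- function(records, species_list) {
  if (length(species_list) == 0) stop("`species_list` is empty")
  key <- paste(records$observer, records$route, records$year,
               records$species, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (observer, route, year, species) rows: ",
         paste(head(unique(gsub("\r", "/", key[dup])), 5), collapse = "; "))
  }
  surveys <- !duplicated(paste(records$observer, records$route, records$year,
                               sep = "\r"))
  base <- records[surveys, setdiff(names(records), c("species", "count")),
                  drop = FALSE]
  full <- merge(base, data.frame(species = species_list,
                                 stringsAsFactors = FALSE))
  have <- paste(full$observer, full$route, full$year, full$species,
                sep = "\r") %in% key
  add <- full[!have, , drop = FALSE]
  if (nrow(add)) {
    add$count <- 0L
    add <- add[, names(records), drop = FALSE]
    out <- rbind(records, add)
  } else {
    out <- records
  }
  rownames(out) <- NULL
  attr(out, "n_added") <- nrow(add)
  out
}

#' Derive minimum observer age
#'
#' "Minimum observer age" is the number of years since the observer's first
#' year of service on any route, with the first year counted as age 1:
#' `observer_age = year - first_service_year + 1`. First service years are
#' taken from the complete historical record (which may begin before the
#' analysis window), not from the filtered analysis data.
#'
#' @param records Count data.frame with `observer` and `year`.
#' @param full_history Either a data.frame with `observer` and
#'   `first_service_year`, or a full record table with `observer` and `year`
#'   (first service year is then the minimum year per observer over all
#'   routes).
#' @return `records` with an `observer_age` column appended.
#' @export
compute_min_observer_age <- function(records, full_history) {
  if ("first_service_year" %in% names(full_history)) {
    first <- setNames(full_history$first_service_year, full_history$observer)
  } else if (all(c("observer", "year") %in% names(full_history))) {
    first <- tapply(full_history$year, full_history$observer, min)
  } else {
    stop("`full_history` needs (observer, first_service_year) or (observer, year)")
  }
  unknown <- setdiff(unique(records$observer), names(first))
  if (length(unknown)) {
    stop("observers absent from full history: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  f <- as.numeric(first[records$observer])
  if (any(records$year < f)) {
    bad <- which(records$year < f)[1]
    stop("record year ", records$year[bad], " precedes observer ",
         records$observer[bad], "'s first service year ", f[bad])
  }
  records$observer_age <- as.integer(records$year - f + 1)
  records
}

#' Exclusion-filter rules
#'
#' @param min_series_years Minimum run of consecutive surveyed years an
#'   observer-route series must have (default 10); gaps reset the run.
#' @param min_observers_per_stratum Minimum distinct observers per
#'   species-stratum (default 3).
#' @param max_age_year_cor Maximum allowed absolute Pearson correlation
#'   between pooled observer ages and calendar year within a
#'   species-stratum (default 0.7) — the age/population confounding guard.
#' @return A list of class `"filter_rules"`.
#' @export
filter_rules <- function(min_series_years = 10,
                         min_observers_per_stratum = 3,
                         max_age_year_cor = 0.7) {
  stopifnot(min_series_years > 0, min_observers_per_stratum > 0,
            max_age_year_cor > 0)
  structure(list(min_series_years = min_series_years,
                 min_observers_per_stratum = min_observers_per_stratum,
                 max_age_year_cor = max_age_year_cor),
            class = "filter_rules")
}

#' Apply the exclusion filters
#'
#' Applies, in this fixed order, the data-quality exclusions of the count
#' pipeline and reports how many records each rule removed:
#' 1. records failing the single-observer / acceptable-weather flags;
#' 2. each observer-route's first calendar year (start-up effect);
#' 3. observer-route series without `min_series_years` consecutive surveyed
#'    years (only years inside a qualifying run are kept);
#' 4. species-strata with fewer than `min_observers_per_stratum` distinct
#'    observers;
#' 5. species-strata where pooled observer age and calendar year correlate
#'    more strongly than `max_age_year_cor` in absolute value (age and
#'    population change confounded).
#'
#' @param records Count table with `observer_age` already present (see
#'   [compute_min_observer_age()]).
#' @param rules A [filter_rules()].
#' @return List with `records` (retained rows) and `report` (class
#'   `"filter_report"`): per-rule removal counts, input and retained totals.
#' @export
apply_filters <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  if (!"observer_age" %in% names(records)) {
    stop("`observer_age` missing; run compute_min_observer_age() first")
  }
  n_input <- nrow(records)
  removed <- c(flags = 0L, first_year = 0L, short_series = 0L,
               few_observers = 0L, confounded = 0L)

  # 1. survey-quality flags
  ok <- rep(TRUE, nrow(records))
  if ("single_observer" %in% names(records)) ok <- ok & records$single_observer
  if ("acceptable_weather" %in% names(records)) ok <- ok & records$acceptable_weather
  removed["flags"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  # 2. first calendar year per observer-route
  series <- paste(records$observer, records$route, sep = "\r")
  first_year <- tapply(records$year, series, min)
  drop2 <- records$year == first_year[series]
  removed["first_year"] <- sum(drop2)
  records <- records[!drop2, , drop = FALSE]

  # 3. >= min_series_years consecutive surveyed years per observer-route
  if (nrow(records)) {
    series <- paste(records$observer, records$route, sep = "\r")
    keep_year <- logical(nrow(records))
    for (s in unique(series)) {
      idx <- series == s
      yrs <- sort(unique(records$year[idx]))
      runs <- cumsum(c(1, diff(yrs) != 1))
      good_runs <- as.integer(names(which(table(runs) >= rules$min_series_years)))
      keep_year[idx] <- records$year[idx] %in% yrs[runs %in% good_runs]
    }
    removed["short_series"] <- sum(!keep_year)
    records <- records[keep_year, , drop = FALSE]
  }

  # 4. >= min_observers_per_stratum distinct observers per species-stratum
  if (nrow(records)) {
    grp <- paste(records$species, records$stratum, sep = "\r")
    nobs <- tapply(records$observer, grp, function(o) length(unique(o)))
    drop4 <- nobs[grp] < rules$min_observers_per_stratum
    removed["few_observers"] <- sum(drop4)
    records <- records[!drop4, , drop = FALSE]
  }

  # 5. age/year confounding guard per species-stratum
  if (nrow(records)) {
    grp <- paste(records$species, records$stratum, sep = "\r")
    keep5 <- logical(nrow(records))
    for (g in unique(grp)) {
      idx <- grp == g
      a <- records$observer_age[idx]
      y <- records$year[idx]
      r <- if (sd(a) > 0 && sd(y) > 0) cor(a, y) else 0
      keep5[idx] <- abs(r) <= rules$max_age_year_cor
    }
    removed["confounded"] <- sum(!keep5)
    records <- records[keep5, , drop = FALSE]
  }

  rownames(records) <- NULL
  report <- structure(list(removed = removed, input = n_input,
                           retained = nrow(records), rules = rules),
                      class = "filter_report")
  stopifnot(sum(removed) + report$retained == n_input)
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$input, "records in,", x$retained, "retained\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  %-14s -%d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Per-species overdispersed Poisson GAMM
#'
#' Fits `log mu = intercept + f_age(observer_age) + f_s(year) per stratum +
#' u_observer` by penalized quasi-Poisson regression (cubic regression-spline
#' bases, REML smoothness selection via mgcv; observer intercepts as a
#' ridge-penalized random-effect smooth). The overdispersion scale is the
#' Pearson chi-square / df estimate, and the age-smooth p-value tests the
#' null of no linear or nonlinear age effect (Wald on the penalized
#' coefficients with effective degrees of freedom, scaled by the dispersion
#' estimate — approximate by construction).
#'
#' Degenerate structures are handled explicitly: the per-stratum year smooths
#' are dropped when only one distinct year is present, the observer term when
#' fewer than two observers remain.
#'
#' @param records Filtered, zero-filled records for one species with
#'   `count`, `observer_age`, `year`, `stratum`, `observer`.
#' @param k Basis dimension per smooth (default 10; shrunk automatically to
#'   the number of distinct covariate values).
#' @param ... Passed to [mgcv::gam()] (e.g. `sp` to fix smoothing
#'   parameters).
#' @return An object of class `"age_gamm"`: the mgcv fit plus `smooth_p`,
#'   `scale` (Pearson overdispersion), `n`, `species`.
#' @export
fit_species_age_gamm <- function(records, k = 10, ...) {
  if (nrow(records) < 30) {
    stop("need >= 30 records to fit the age GAMM (got ", nrow(records), ")")
  }
  if (length(unique(records$species)) > 1) {
    stop("records span multiple species; fit one species at a time")
  }
  d <- data.frame(count = as.integer(records$count),
                  observer_age = as.numeric(records$observer_age),
                  year = as.numeric(records$year),
                  stratum_f = factor(records$stratum),
                  observer_f = factor(records$observer))
  k_age <- min(k, length(unique(d$observer_age)) - 1L)
  if (k_age < 3) stop("too few distinct observer ages (need >= 4)")
  terms <- sprintf("s(observer_age, k = %d, bs = 'cr')", k_age)
  if (length(unique(d$year)) >= 4) {
    k_yr <- min(k, length(unique(d$year)) - 1L)
    if (nlevels(d$stratum_f) > 1) {
      terms <- c(terms, sprintf("s(year, by = stratum_f, k = %d, bs = 'cr')", k_yr))
    } else {
      terms <- c(terms, sprintf("s(year, k = %d, bs = 'cr')", k_yr))
    }
  }
  if (nlevels(d$observer_f) >= 2) terms <- c(terms, "s(observer_f, bs = 're')")
  form <- as.formula(paste("count ~", paste(terms, collapse = " + ")))
  m <- tryCatch(
    mgcv::gam(form, family = stats::quasipoisson(), data = d,
              method = "REML", ...),
    error = function(e) stop("GAMM fit failed (possibly rank-deficient ",
                             "design, e.g. a single year per stratum): ",
                             conditionMessage(e))
  )
  if (!m$converged) warning("penalized IRLS did not converge")
  st <- summary(m)$s.table
  age_row <- grep("observer_age", rownames(st))
  structure(list(model = m, smooth_p = unname(st[age_row, "p-value"]),
                 edf = unname(st[age_row, "edf"]),
                 scale = summary(m)$dispersion,
                 converged = m$converged,
                 n = nrow(d), species = records$species[1]),
            class = "age_gamm")
}

#' Proportional age-effect curve for one fitted species
#'
#' Evaluates the fitted age smooth on an age grid with all other covariates
#' at reference (the age term is isolated, so observer intercepts and year
#' smooths drop out) and normalizes to the first year of service:
#' `exp(f_age(a) - f_age(1))`, which is exactly 1 at age 1. The pointwise 95%
#' band uses the smooth's standard errors on the log scale.
#'
#' @param fit An [`age_gamm`][fit_species_age_gamm()].
#' @param ages Integer age grid (default 1:39).
#' @return data.frame with `age`, `estimate`, `lo`, `hi`.
#' @export
age_effect_curve <- function(fit, ages = 1:39) {
  stopifnot(inherits(fit, "age_gamm"))
  m <- fit$model
  d <- m$model
  # reference values for whatever covariates this species' model retained:
  # median year, first stratum, first observer (the terms prediction isolates
  # the age smooth, so these drop out of the returned curve)
  nd <- data.frame(observer_age = as.numeric(ages))
  for (v in setdiff(names(d), c("count", "observer_age"))) {
    nd[[v]] <- if (is.factor(d[[v]])) {
      factor(levels(d[[v]])[1], levels = levels(d[[v]]))
    } else {
      median(d[[v]])
    }
  }
  pr <- predict(m, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep("observer_age", colnames(pr$fit))
  f <- pr$fit[, col]
  se <- pr$se.fit[, col]
  f1 <- f[ages == 1]
  if (length(f1) == 0) f1 <- f[1]
  est <- exp(f - f1)
  data.frame(age = ages, estimate = est,
             lo = exp(f - f1 - 1.96 * se),
             hi = exp(f - f1 + 1.96 * se))
}

#' Pooled proportional-change curves by vocalization group
#'
#' Second-stage smooths: per-species normalized age curves (from
#' [age_effect_curve()]) are pooled within each vocalization group (species
#' weighted equally) and a spline is fitted to the pooled log proportional
#' changes. The returned curve is renormalized so its value at age 1 is
#' exactly 1, with a pointwise 95% band and the smooth-term p-value. Empty
#' groups are skipped with a message.
#'
#' @param fits Named list of [`age_gamm`][fit_species_age_gamm()] fits
#'   (names are species).
#' @param groups Either a named character vector (species -> group label) or
#'   a data.frame with `species` and `group8` columns (e.g. from
#'   [classify_species_set()]).
#' @param ages Age grid.
#' @param k Basis dimension of the second-stage smooth.
#' @return Named list (one per group) of `"age_effect_curve_group"` objects:
#'   `curve` (data.frame `age`, `estimate`, `lo`, `hi`), `p_value`,
#'   `n_species`, `n_records`, `group`.
#' @export
group_proportional_curve <- function(fits, groups, ages = 1:39, k = 10) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group8, groups$species)
  }
  out <- list()
  for (g in unique(groups)) {
    sps <- intersect(names(groups)[groups == g], names(fits))
    if (length(sps) == 0) {
      message("group '", g, "' has no fitted species; skipped")
      next
    }
    pooled <- do.call(rbind, lapply(sps, function(sp) {
      cv <- age_effect_curve(fits[[sp]], ages)
      data.frame(species = sp, age = cv$age, log_prop = log(cv$estimate))
    }))
    k2 <- min(k, length(unique(pooled$age)) - 1L)
    m2 <- mgcv::gam(log_prop ~ s(age, k = k2, bs = "cr"), data = pooled,
                    method = "REML")
    nd <- data.frame(age = as.numeric(ages))
    pr <- predict(m2, newdata = nd, se.fit = TRUE)
    f1 <- pr$fit[ages == 1]
    if (length(f1) == 0) f1 <- pr$fit[1]
    curve <- data.frame(age = ages,
                        estimate = exp(pr$fit - f1),
                        lo = exp(pr$fit - f1 - 1.96 * pr$se.fit),
                        hi = exp(pr$fit - f1 + 1.96 * pr$se.fit))
    st <- summary(m2)$s.table
    out[[g]] <- structure(
      list(curve = curve, p_value = unname(st[1, "p-value"]),
           n_species = length(sps),
           n_records = sum(vapply(sps, function(sp) fits[[sp]]$n, 0)),
           group = g),
      class = "age_effect_curve_group")
  }
  out
}
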