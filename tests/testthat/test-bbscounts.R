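mk_counts <- function(stratum, route, year, observer, species, count) {
  data.frame(stratum = stratum, route = route, year = year,
             observer = observer, species = species, count = count,
             single_observer = TRUE, acceptable_weather = TRUE,
             stringsAsFactors = FALSE)
}

test_that("zero_fill completes route-years against the species list", {
  rec <- mk_counts("S1", "R1", c(1990, 1990, 1991, 1991),
                   "o1", c("A", "B", "A", "C"), 1:4)
  out <- zero_fill(rec, c("A", "B", "C"))
  expect_equal(attr(out, "n_added"), 2)  # 2 route-years x 3 species - 4 rows
  expect_equal(nrow(out), 6)
  added <- out[out$count == 0, ]
  expect_setequal(paste(added$year, added$species), c("1990 C", "1991 B"))
  # idempotent
  again <- zero_fill(out, c("A", "B", "C"))
  expect_equal(attr(again, "n_added"), 0)
  expect_equal(nrow(again), 6)
  # duplicates are an error
  expect_error(zero_fill(rbind(rec, rec[1, ]), c("A", "B")), "duplicate")
})

test_that("zero_fill adds exactly the counted number of zeros at scale", {
  # 50 route-years x 20 species with 613 rows present -> 387 zeros
  set.seed(81)
  ry <- data.frame(route = rep(sprintf("R%02d", 1:10), each = 5),
                   year = rep(1991:1995, 10))
  full <- merge(ry, data.frame(species = sprintf("sp%02d", 1:20)))
  full$stratum <- "S1"
  full$observer <- paste0("o_", full$route)
  full$count <- rpois(nrow(full), 3)
  full$single_observer <- TRUE
  full$acceptable_weather <- TRUE
  present <- full[sample(nrow(full), 613), ]
  out <- zero_fill(present, sprintf("sp%02d", 1:20))
  expect_equal(attr(out, "n_added"), 50 * 20 - 613)
})

test_that("minimum observer age counts years since first service", {
  rec <- mk_counts("S1", "R1", c(1980, 1970), c("a", "b"), "A", 0)
  hist <- data.frame(observer = c("a", "b"),
                     first_service_year = c(1980, 1966))
  out <- compute_min_observer_age(rec, hist)
  expect_equal(out$observer_age, c(1, 5))
  # first year taken over all routes the observer ever served
  full <- mk_counts("S1", c("R1", "R2", "R2"), c(1975, 1971, 1972),
                    "c", "A", 0)
  out2 <- compute_min_observer_age(full[1, ], full)
  expect_equal(out2$observer_age, 5)
  expect_error(
    compute_min_observer_age(mk_counts("S1", "R1", 1960, "a", "A", 0), hist),
    "precedes")
})

test_that("filters implement the exclusion rules in order", {
  base <- function(years, obs, route) {
    r <- mk_counts("S1", route, years, obs, "A", 1)
    r$observer_age <- years - min(years) + 1
    r
  }
  # 12 consecutive years: first dropped, 11 kept
  r12 <- base(1990:2001, "o1", "R1")
  # 12 years with one gap (runs 5 + 7): fully dropped
  rgap <- base(setdiff(1990:2002, 1995), "o2", "R2")
  # 9 consecutive: fully dropped
  r9 <- base(1990:1998, "o3", "R3")
  # 15 consecutive: first dropped, 14 kept
  r15 <- base(1990:2004, "o4", "R4")
  # 13 consecutive (third surviving observer, needed for rule 4)
  r13 <- base(1992:2004, "o5", "R5")
  rec <- rbind(r12, rgap, r9, r15, r13)
  # decorrelate pooled age and year to keep rule 5 quiet: stagger starts
  rec$observer_age[rec$observer == "o4"] <-
    rec$year[rec$observer == "o4"] - 1977
  res <- apply_filters(rec)
  rep <- res$report
  expect_equal(rep$input, nrow(rec))
  expect_equal(unname(rep$removed["first_year"]), 5)
  expect_equal(unname(rep$removed["short_series"]), 11 + 8)
  expect_equal(unname(rep$removed["few_observers"]), 0)
  expect_equal(rep$retained, 11 + 14 + 12)
  expect_equal(sum(rep$removed) + rep$retained, rep$input)
  expect_setequal(unique(res$records$observer), c("o1", "o4", "o5"))
})

test_that("the confounding guard drops perfectly collinear strata", {
  # every observer's age equals year - 1960: r = 1, stratum dropped
  rec <- do.call(rbind, lapply(1:3, function(i) {
    r <- mk_counts("S1", paste0("R", i), 1990:2003, paste0("o", i), "A", 1)
    r$observer_age <- r$year - 1960
    r
  }))
  res <- apply_filters(rec)
  expect_equal(res$report$retained, 0)
  expect_gt(res$report$removed["confounded"], 0)
  # a 2-observer stratum falls to the few-observers rule instead
  rec2 <- rec[rec$observer != "o3", ]
  rec2$observer_age <- rep(c(3, 8), each = 14) + rep(0:13, 2)
  res2 <- apply_filters(rec2)
  expect_equal(unname(res2$report$removed["few_observers"]),
               res2$report$input - res2$report$removed[["first_year"]])
})

test_that("zero-fill before filtering is order-sensitive on the fixture", {
  # A is reported on three staggered-tenure routes throughout; B is really
  # reported only once, by o1 in 1991. Zero-filling first gives B the full
  # survey coverage, so it passes the 3-observer rule and its real count
  # survives; filtering first sees B as a one-observer species, drops it,
  # and a later zero-fill can only resurrect it as zeros.
  recA <- rbind(mk_counts("S1", "R1", 1990:2001, "o1", "A", 2),
                mk_counts("S1", "R2", 1990:2001, "o2", "A", 3),
                mk_counts("S1", "R3", 1990:2001, "o3", "A", 1))
  rec <- rbind(recA, mk_counts("S1", "R1", 1991, "o1", "B", 5))
  hist <- data.frame(observer = c("o1", "o2", "o3"),
                     first_service_year = c(1990, 1984, 1978))
  zeros_first <- apply_filters(
    compute_min_observer_age(zero_fill(rec, c("A", "B")), hist))
  filter_first <- apply_filters(compute_min_observer_age(rec, hist))
  expect_equal(zeros_first$report$retained, 66)
  expect_equal(filter_first$report$retained, 33)
  expect_equal(unname(filter_first$report$removed[["few_observers"]]), 1)
  refilled <- zero_fill(filter_first$records[, names(rec)], c("A", "B"))
  expect_true(any(zeros_first$records$species == "B" &
                    zeros_first$records$count == 5))
  expect_false(any(refilled$species == "B" & refilled$count == 5))
})

test_that("the age GAMM collapses to Poisson GLM at infinite smoothing", {
  # single observer and year: the model reduces to intercept + age smooth,
  # and an infinite smoothing parameter collapses the cubic spline to the
  # linear null space
  set.seed(91)
  n <- 400
  age <- sample(1:20, n, replace = TRUE)
  rec <- mk_counts("S1", "R1", 2000, "o1", "A",
                   rpois(n, exp(1 + 0.05 * age)))
  rec$observer_age <- age
  fit <- fit_species_age_gamm(rec, sp = 1e12,
                              control = mgcv::gam.control(epsilon = 1e-11))
  ml <- glm(count ~ observer_age, family = poisson(),
            data = data.frame(count = rec$count, observer_age = age),
            control = glm.control(epsilon = 1e-11))
  expect_equal(unname(fitted(fit$model)), unname(fitted(ml)),
               tolerance = 1e-6)
})

test_that("the age GAMM recovers an intercept-only truth", {
  set.seed(92)
  n <- 500
  rec <- mk_counts("S1", "R1", 2000, sprintf("o%d", 1:n), "A",
                   rpois(n, 10))
  rec$observer_age <- sample(1:25, n, replace = TRUE)
  fit <- fit_species_age_gamm(rec)
  expect_lt(max(abs(fitted(fit$model) - mean(rec$count))) / mean(rec$count),
            0.1)
  expect_error(fit_species_age_gamm(rec[1:10, ]), ">= 30")
  rec2 <- rec; rec2$species[1] <- "B"
  expect_error(fit_species_age_gamm(rec2), "one species")
})

test_that("age-effect curves are normalized with sane bands", {
  rec <- filtered_bbs_records(bbs_recovery_config(seed = 93))
  fit <- fit_species_age_gamm(rec)
  cv <- age_effect_curve(fit, 1:39)
  expect_equal(cv$estimate[1], 1)
  expect_true(all(is.finite(cv$lo) & is.finite(cv$hi)))
  expect_true(all(cv$lo <= cv$estimate & cv$estimate <= cv$hi))
})

test_that("group curves pool species and keep the age-1 anchor", {
  fits <- list()
  for (s in 1:3) {
    rec <- filtered_bbs_records(bbs_recovery_config(seed = 200 + s))
    rec$species <- paste0("SP", s)
    fits[[paste0("SP", s)]] <- fit_species_age_gamm(rec)
  }
  groups <- c(SP1 = "High Monotone", SP2 = "High Monotone",
              SP3 = "High Monotone")
  curves <- group_proportional_curve(fits, groups, ages = 1:39)
  expect_length(curves, 1)
  cu <- curves[["High Monotone"]]
  expect_equal(cu$curve$estimate[1], 1)
  expect_equal(cu$n_species, 3)
  expect_true(all(cu$curve$lo <= cu$curve$estimate &
                    cu$curve$estimate <= cu$curve$hi))
  # single-species group: second-stage smooth reproduces the species curve
  one <- group_proportional_curve(fits["SP1"], groups["SP1"], ages = 1:39)
  species_curve <- age_effect_curve(fits$SP1, 1:39)$estimate
  expect_lt(max(abs(one[[1]]$curve$estimate - species_curve)), 0.01)
  # empty group skipped with a message
  expect_message(
    out <- group_proportional_curve(fits["SP1"], c(SP9 = "Low Monotone")),
    "skipped")
  expect_length(out, 0)
})
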