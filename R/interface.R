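#' Registered table schemas
#'
#' Column names and types for every CSV the pipeline reads or writes.
#' `read_table()`/`write_table()` enforce them strictly.
#'
#' @return Named list of schemas (each a named character vector of types
#'   `"integer"`, `"double"`, `"character"`, `"logical"`).
#' @export
table_schemas <- function() {
  list(
    detections = c(square = "integer", year = "integer",
                   observer = "character", age_class = "character",
                   gender = "character", effort = "double",
                   species = "character", detected = "integer",
                   first_atlas = "integer"),
    counts = c(stratum = "character", route = "character", year = "integer",
               observer = "character", species = "character",
               count = "integer", single_observer = "logical",
               acceptable_weather = "logical"),
    observers = c(observer = "character", first_service_year = "integer"),
    vocal_classes = c(species = "character", peak_khz = "double",
                      sd = "double", heterogeneity = "character",
                      freq_group = "character", group8 = "character"),
    beta2 = c(species = "character", beta2 = "double", beta2_var = "double",
              ci_lo = "double", ci_hi = "double",
              significant_negative = "logical"),
    trends = c(species = "character", trend_a = "double",
               trend_a_ci_width = "double", trend_b = "double",
               trend_b_n_routes = "double"),
    curves = c(group = "character", age = "integer", estimate = "double",
               lo = "double", hi = "double")
  )
}

check_cells <- function(raw, types, path) {
  for (col in names(types)) {
    v <- raw[[col]]
    bad <- switch(types[[col]],
      integer = which(!grepl("^-?[0-9]+$", v) & v != "NA"),
      double = which(is.na(suppressWarnings(as.numeric(v))) & v != "NA"),
      logical = which(!v %in% c("TRUE", "FALSE", "NA")),
      character = integer(0))
    if (length(bad)) {
      stop("type violation in ", path, ": column `", col, "` row ", bad[1],
           " has value \"", v[bad[1]], "\" (expected ", types[[col]], ")")
    }
  }
}

#' Read a typed table
#'
#' Strictly typed CSV reader: the file must have exactly the registered
#' columns of `schema`, and every cell must parse as the declared type
#' (an integer column containing `3.5` is an error naming the column and
#' row). Round-trips with [write_table()] are lossless.
#'
#' @param path CSV path.
#' @param schema Schema name (see [table_schemas()]).
#' @return A data.frame with the declared column types.
#' @export
read_table <- function(path, schema) {
  types <- table_schemas()[[schema]]
  if (is.null(types)) stop("unknown schema: ", schema)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(types), names(raw))
  extra <- setdiff(names(raw), names(types))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (length(extra)) stop("unexpected column(s) in ", path, ": ",
                          paste(extra, collapse = ", "))
  check_cells(raw, types, path)
  out <- raw[, names(types), drop = FALSE]
  for (col in names(types)) {
    out[[col]] <- switch(types[[col]],
      integer = as.integer(out[[col]]),
      double = as.numeric(out[[col]]),
      logical = as.logical(out[[col]]),
      character = out[[col]])
  }
  out
}

#' Write a typed table
#'
#' @param records Data.frame matching the schema's columns.
#' @param path Output CSV path.
#' @param schema Schema name.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  types <- table_schemas()[[schema]]
  if (is.null(types)) stop("unknown schema: ", schema)
  miss <- setdiff(names(types), names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(records[, names(types), drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Deterministic per-stage seed
#'
#' Derives an independent, reproducible seed for each pipeline stage from the
#' master seed and the stage name (polynomial string hash mod 2^31 - 1), so
#' stages can be rerun in isolation.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
stage_seed <- function(master, stage) {
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h + 1)
}

#' Pipeline run configuration
#'
#' One JSON-serializable document driving [run_all()]. Every numeric default
#' that encodes an analysis rule carries the canonical value: vocalization
#' thresholds 3/6/7 kHz, young/old age cutoffs 40/50, the 10-consecutive-year
#' series rule, 3 observers per stratum, the 0.7 age-year correlation guard,
#' the 100-detection minimum per occupancy species, and 95% intervals.
#'
#' The demo-scale species table drives the simulators: each row gives a
#' species label, its true peak frequency, whether its song is a pure tone
#' (monotone) or a tone stack (heterogeneous), its true logit-scale age
#' contrast `beta2_true`, and its true proportional count decline by the
#' maximum observer age.
#'
#' @param seed Master seed; per-stage seeds derive via [stage_seed()].
#' @param out_dir Output directory.
#' @param stages Named logical vector enabling each stage.
#' @param species Species table (data.frame: `species`, `peak_khz`,
#'   `monotone`, `beta2_true`, `decline_39`).
#' @param n_squares,atlas_years Atlas simulator size.
#' @param n_strata,routes_per_stratum,bbs_years BBS simulator size.
#' @param mcmc_chains,mcmc_iter Occupancy chain settings.
#' @param thresholds_khz,age_young_max,age_old_min,min_series_years,
#'   min_observers_per_stratum,max_age_year_cor,min_detections,ci_level
#'   Analysis rule constants (documented defaults; override knowingly).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("obsaging_run_"),
                       stages = c(simulate = TRUE, classify = TRUE,
                                  fit_occupancy = TRUE, run_bbs = TRUE,
                                  link_trends = TRUE),
                       species = default_species_table(),
                       n_squares = 150, atlas_years = 2001:2003,
                       n_strata = 3, routes_per_stratum = 4,
                       bbs_years = 1986:2007,
                       mcmc_chains = 2, mcmc_iter = 6000,
                       thresholds_khz = c(3, 6, 7),
                       age_young_max = 40, age_old_min = 50,
                       min_series_years = 10,
                       min_observers_per_stratum = 3,
                       max_age_year_cor = 0.7,
                       min_detections = 100,
                       ci_level = 0.95) {
  structure(as.list(environment()), class = "run_config")
}

#' Default demo species table
#'
#' Ten synthetic species spanning the four frequency groups, balanced five
#' pure-tone (monotone) against five tone-stack (heterogeneous) songs so the
#' cohort median splits the classes cleanly. Only the monotone species at or
#' above 6 kHz carry a true age-related detection loss (the hearing-loss
#' world); their `beta2` grows more negative with pitch.
#'
#' @return data.frame with `species`, `peak_khz`, `monotone`, `beta2_true`,
#'   `decline_39`.
#' @export
default_species_table <- function() {
  peak <- c(2.0, 2.5, 4.0, 4.6, 5.2, 6.2, 6.6, 7.0, 7.8, 8.4)
  monotone <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                TRUE)
  beta2 <- ifelse(monotone & peak >= 6, -0.8 * (peak - 5), 0)
  data.frame(species = sprintf("SP%02d", seq_along(peak)),
             peak_khz = peak, monotone = monotone, beta2_true = beta2,
             decline_39 = ifelse(monotone & peak >= 6, 0.5, 0.15),
             stringsAsFactors = FALSE)
}

#' Load a run configuration from JSON
#'
#' Unknown keys are rejected; known keys override the defaults of
#' [run_config()].
#'
#' @param path JSON file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(doc$species)) doc$species <- as.data.frame(doc$species)
  if (!is.null(doc$stages)) doc$stages <- unlist(doc$stages)
  do.call(run_config, doc)
}

md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}

#' Run the full pipeline
#'
#' Executes simulate -> classify -> fit-occupancy -> run-bbs -> link-trends
#' on a [run_config()], skipping disabled stages, writing every intermediate
#' table as CSV under `config$out_dir`, and returning a run manifest (config
#' hash, per-stage seeds and row counts, output file digests). Identical
#' config and seeds reproduce identical digests. A stage failure aborts with
#' the stage name; the manifest written so far is attached to the error
#' condition.
#'
#' @param config A [run_config()].
#' @return A `"run_manifest"` list.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(config_hash = config_hash(config),
                   master_seed = config$seed,
                   stage_seeds = list(), stages = character(0),
                   rows = list(), digests = list())
  sp <- config$species
  run_stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    s <- stage_seed(config$seed, name)
    manifest$stage_seeds[[name]] <<- s
    res <- tryCatch(fn(s), error = function(e) {
      cond <- simpleError(paste0("stage `", name, "` failed: ",
                                 conditionMessage(e)))
      cond$manifest <- manifest
      stop(cond)
    })
    manifest$stages <<- c(manifest$stages, name)
    manifest$rows[[name]] <<- res
    invisible(NULL)
  }

  run_stage("simulate", function(s) {
    det <- list()
    cnt <- list()
    obs <- list()
    for (i in seq_len(nrow(sp))) {
      a <- simulate_atlas(atlas_sim_config(
        n_squares = config$n_squares, years = config$atlas_years,
        beta2 = sp$beta2_true[i], species = sp$species[i],
        seed = (s + i) %% 2147483647))
      det[[i]] <- a$detections
      b <- simulate_bbs(bbs_sim_config(
        n_strata = config$n_strata,
        routes_per_stratum = config$routes_per_stratum,
        years = config$bbs_years,
        tenure_dist = function(n) sample(12:30, n, replace = TRUE),
        stratum_trend_fn = function(year, stratum) 0,
        age_decline_fn = local({
          dec <- sp$decline_39[i]
          function(age) log(1 - dec * (age - 1) / 38)
        }),
        species = sp$species[i], seed = (s + 100 + i) %% 2147483647))
      # observer ids are species-scoped: the demo gives each species its own
      # simulated route set, so prefix to keep ids globally unique
      b$counts$observer <- paste0(sp$species[i], "_", b$counts$observer)
      b$observers$observer <- paste0(sp$species[i], "_", b$observers$observer)
      cnt[[i]] <- b$counts
      obs[[i]] <- b$observers
      comps <- if (sp$monotone[i]) {
        data.frame(freq_khz = sp$peak_khz[i], amp = 1, sweep_to_khz = NA)
      } else {
        data.frame(freq_khz = sp$peak_khz[i] + seq(-1.5, 1.5, length.out = 9),
                   amp = c(rep(0.6, 4), 1, rep(0.6, 4)), sweep_to_khz = NA)
      }
      w <- synthesize_vocalization(
        vocal_spec(duration = 0.5, components = comps),
        seed = (s + 200 + i) %% 2147483647)
      write_wav(w, out(paste0(sp$species[i], ".wav")))
    }
    write_table(do.call(rbind, det), out("detections.csv"), "detections")
    write_table(do.call(rbind, cnt), out("counts.csv"), "counts")
    ob <- unique(do.call(rbind, obs))
    write_table(ob, out("bbs_observers.csv"), "observers")
    # synthetic "published" trends: proportional to the true age effect plus noise
    set.seed(s)
    tr <- data.frame(species = sp$species,
                     trend_a = 1.5 * sp$beta2_true + rnorm(nrow(sp), 0, 0.15),
                     trend_a_ci_width = runif(nrow(sp), 0.5, 2),
                     trend_b = 1.5 * sp$beta2_true + rnorm(nrow(sp), 0, 0.15),
                     trend_b_n_routes = round(runif(nrow(sp), 20, 200)))
    write_table(tr, out("trends_synthetic.csv"), "trends")
    jsonlite::write_json(sp, out("truth.json"), digits = NA)
    list(detections = nrow(do.call(rbind, det)),
         counts = nrow(do.call(rbind, cnt)))
  })

  run_stage("classify", function(s) {
    waves <- setNames(as.list(out(paste0(sp$species, ".wav"))), sp$species)
    cls <- classify_species_set(waves)
    write_table(cls, out("vocal_classes.csv"), "vocal_classes")
    list(species = nrow(cls))
  })

  run_stage("fit_occupancy", function(s) {
    det <- read_table(out("detections.csv"), "detections")
    res <- lapply(split(det, det$species), function(d) {
      fit <- fit_occupancy_mcmc(d, occu_model_spec(
        n_chains = config$mcmc_chains, n_iter = config$mcmc_iter,
        min_detections = config$min_detections,
        enforce_min_detections = FALSE, seed = s))
      b <- extract_beta2(fit, allow_nonconverged = TRUE)
      data.frame(species = d$species[1], beta2 = b$estimate,
                 beta2_var = b$variance, ci_lo = b$ci[1], ci_hi = b$ci[2],
                 significant_negative = b$significant_negative)
    })
    tab <- do.call(rbind, res)
    rownames(tab) <- NULL
    write_table(tab, out("beta2.csv"), "beta2")
    list(species = nrow(tab))
  })

  run_stage("run_bbs", function(s) {
    cnt <- read_table(out("counts.csv"), "counts")
    hist <- read_table(out("bbs_observers.csv"), "observers")
    filled <- cnt # per-species simulations are already complete tables
    aged <- compute_min_observer_age(filled, hist)
    fl <- apply_filters(aged, filter_rules(
      min_series_years = config$min_series_years,
      min_observers_per_stratum = config$min_observers_per_stratum,
      max_age_year_cor = config$max_age_year_cor))
    cls <- read_table(out("vocal_classes.csv"), "vocal_classes")
    fits <- lapply(split(fl$records, fl$records$species),
                   fit_species_age_gamm)
    curves <- group_proportional_curve(fits, cls,
                                       ages = 1:max(fl$records$observer_age))
    ctab <- do.call(rbind, lapply(curves, function(cu) {
      data.frame(group = cu$group, age = cu$curve$age,
                 estimate = cu$curve$estimate, lo = cu$curve$lo,
                 hi = cu$curve$hi)
    }))
    rownames(ctab) <- NULL
    write_table(ctab, out("age_curves.csv"), "curves")
    list(retained = fl$report$retained, removed = sum(fl$report$removed),
         groups = length(curves))
  })

  run_stage("link_trends", function(s) {
    b2 <- read_table(out("beta2.csv"), "beta2")
    cls <- read_table(out("vocal_classes.csv"), "vocal_classes")
    tr <- read_table(out("trends_synthetic.csv"), "trends")
    rows <- merge(merge(b2, cls, by = "species"), tr, by = "species")
    ph <- tryCatch(posthoc_highfreq_linear(rows), error = function(e) NULL)
    co <- tryCatch(correlate_beta2_trend(rows, "a"), error = function(e) NULL)
    summ <- data.frame(
      quantity = c("posthoc_slope", "posthoc_p", "pearson_r_a", "pearson_p_a"),
      value = c(if (is.null(ph)) NA else unname(ph$coefficients["peak_khz"]),
                if (is.null(ph)) NA else ph$p_slope,
                if (is.null(co)) NA else co$r,
                if (is.null(co)) NA else co$p))
    write.csv(summ, out("linkage_summary.csv"), row.names = FALSE)
    list(species = nrow(rows))
  })

  files <- sort(list.files(config$out_dir, pattern = "\\.(csv|json)$",
                           full.names = TRUE))
  manifest$digests <- setNames(as.list(md5_of(files)), basename(files))
  structure(manifest, class = "run_manifest")
}

config_hash <- function(config) {
  plain <- lapply(unclass(config), function(x) {
    if (is.function(x)) deparse(x) else x
  })
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (config", substr(x$config_hash, 1, 8), ")\n")
  cat("Stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("Outputs:\n")
  for (f in names(x$digests)) cat(" ", f, substr(x$digests[[f]], 1, 8), "\n")
  invisible(x)
}
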