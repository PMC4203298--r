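#' Averaged-periodogram power spectrum
#'
#' Welch-style spectral estimate: the waveform is cut into Hann-windowed
#' segments of `fft_size` samples with the given overlap, per-segment
#' modified periodograms are averaged, and a one-sided density on a fixed
#' frequency grid (kHz) is returned. This is the estimator behind peak
#' (dominant) frequency and spectral-heterogeneity classification.
#'
#' @param wave A `"waveform"` (list with `samples`, `rate`) or numeric vector.
#' @param rate Sampling rate in Hz when `wave` is a bare vector.
#' @param fft_size Segment/FFT length (samples); default 4096.
#' @param overlap Fractional segment overlap in \[0, 1); default 0.5.
#' @return A `"power_spectrum"`: list with `frequencies` (kHz, strictly
#'   increasing up to Nyquist), `power` (nonnegative density) and `params`.
#' @export
compute_power_spectrum <- function(wave, rate = NULL, fft_size = 4096,
                                   overlap = 0.5) {
  if (inherits(wave, "waveform")) {
    samples <- wave$samples
    rate <- wave$rate
  } else {
    samples <- as.numeric(wave)
    if (is.null(rate)) stop("`rate` required when `wave` is a bare vector")
  }
  stopifnot(fft_size >= 8, overlap >= 0, overlap < 1)
  if (length(samples) < fft_size) {
    stop("waveform too short: ", length(samples), " samples; at least ",
         fft_size, " (one FFT segment) required")
  }
  w <- 0.5 * (1 - cos(2 * pi * (0:(fft_size - 1)) / (fft_size - 1))) # Hann
  step <- max(1L, as.integer(round(fft_size * (1 - overlap))))
  starts <- seq(1L, length(samples) - fft_size + 1L, by = step)
  acc <- numeric(fft_size %/% 2 + 1L)
  scale <- rate * sum(w^2)
  for (s in starts) {
    seg <- samples[s:(s + fft_size - 1L)] * w
    sp <- abs(fft(seg))^2 / scale
    one <- sp[seq_len(length(acc))]
    # fold the two-sided density, leaving DC and Nyquist unscaled
    one[2:(length(one) - 1L)] <- 2 * one[2:(length(one) - 1L)]
    acc <- acc + one
  }
  power <- acc / length(starts)
  freqs <- (seq_along(power) - 1) * rate / fft_size / 1000
  structure(list(frequencies = freqs, power = power,
                 params = list(fft_size = fft_size, overlap = overlap,
                               rate = rate, n_segments = length(starts))),
            class = "power_spectrum")
}

#' Peak (dominant) frequency of a power spectrum
#'
#' The frequency at the global maximum of the power spectrum; ties are broken
#' toward the lowest frequency (deterministic, and conservative toward
#' better-heard frequencies).
#'
#' @param spectrum A `"power_spectrum"` (or list with `frequencies`, `power`).
#' @return Peak frequency in kHz.
#' @export
peak_frequency <- function(spectrum) {
  p <- spectrum$power
  if (length(p) == 0 || max(p) <= 0) {
    stop("degenerate spectrum: all power values are zero")
  }
  spectrum$frequencies[which.max(p)] # which.max: first == lowest frequency
}

#' Spectral heterogeneity statistic
#'
#' Standard deviation of the power values across frequency bins, computed on
#' linear power after per-spectrum normalization to unit total power (which
#' makes the statistic invariant to recording amplitude). A dB mode (SD of
#' `10*log10` relative power, floored at -120 dB) is available behind
#' `db_scale` for comparison.
#'
#' @param spectrum A `"power_spectrum"`.
#' @param db_scale Compute the SD on the dB scale instead of linear power.
#' @return The SD (sample SD, `n - 1` denominator).
#' @export
spectrum_sd <- function(spectrum, db_scale = FALSE) {
  p <- spectrum$power
  if (length(p) < 2 || max(p) <= 0) {
    stop("degenerate spectrum: all power values are zero")
  }
  if (db_scale) {
    db <- 10 * log10(pmax(p / max(p), 1e-12))
    return(sd(db))
  }
  sd(p / sum(p))
}

#' Monotone/heterogeneous split by cohort median
#'
#' A species is "monotone" when its spectrum SD is at or below the median SD
#' of the full supplied cohort, "heterogeneous" otherwise. The median is
#' always computed over all values supplied (the reference cohort), so the
#' labels depend on the cohort, not on input order.
#'
#' @param sds Numeric vector of per-species spectrum SDs (names preserved).
#' @return Character vector `"monotone"` / `"heterogeneous"`.
#' @export
classify_heterogeneity <- function(sds) {
  if (length(sds) == 0) stop("empty SD vector")
  if (length(sds) < 2) stop("need at least 2 species to take a cohort median")
  out <- ifelse(sds <= median(sds), "monotone", "heterogeneous")
  names(out) <- names(sds)
  out
}

#' Frequency-group assignment
#'
#' Bins a peak frequency into the four hearing-loss-motivated groups with
#' half-open thresholds at 3, 6 and 7 kHz: low (< 3), notch (3 to < 6, the
#' noise-induced-hearing-loss band), medium (6 to < 7) and high (>= 7).
#'
#' @param peak Peak frequency (kHz), strictly positive; vectorized.
#' @return Character vector in `c("low", "notch", "medium", "high")`.
#' @export
assign_frequency_group <- function(peak) {
  if (any(!is.finite(peak)) || any(peak <= 0)) {
    stop("peak frequency must be a positive, finite kHz value")
  }
  as.character(cut(peak, breaks = c(0, 3, 6, 7, Inf), right = FALSE,
                   labels = c("low", "notch", "medium", "high")))
}

group8_label <- function(freq_group, heterogeneity) {
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  paste(cap(freq_group), cap(heterogeneity))
}

#' Classify a set of species vocalizations into the eight groups
#'
#' For each species: read/accept its recordings, estimate each recording's
#' power spectrum, average the unit-normalized spectra (the per-species
#' aggregate), then take the peak frequency and spectrum SD. Heterogeneity is
#' the cohort-median split over all species supplied, and the final label
#' crosses frequency group with heterogeneity (e.g. "High Monotone").
#' Unreadable recordings are skipped with a logged failure; the run continues.
#'
#' @param x Named list, one element per species. Each element is a
#'   `"waveform"`, a WAV file path, a `"power_spectrum"`, or a list of those
#'   (multiple recordings, averaged).
#' @param fft_size,overlap Spectral parameters, see
#'   [compute_power_spectrum()].
#' @param db_scale Compute spectrum SDs on the dB scale (default `TRUE`).
#'   On the dB scale a narrowband (single-pitch) song leaves most bins near
#'   the noise floor, giving a *small* SD, so the at-or-below-median rule
#'   selects it as monotone; on linear power the direction inverts (a pure
#'   tone concentrates all power in one bin and maximizes the SD), so linear
#'   mode is offered only for comparison.
#' @return A data.frame with columns `species`, `peak_khz`, `sd`,
#'   `heterogeneity`, `freq_group`, `group8`; failed inputs are listed in
#'   `attr(, "failures")`.
#' @export
classify_species_set <- function(x, fft_size = 4096, overlap = 0.5,
                                 db_scale = TRUE) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("`x` must be a named list (one element per species)")
  }
  if (length(x) < 2) stop("need at least 2 species (median split)")
  failures <- character(0)
  as_spectrum <- function(rec) {
    if (inherits(rec, "power_spectrum")) return(rec)
    if (is.character(rec)) rec <- read_wav(rec)
    compute_power_spectrum(rec, fft_size = fft_size, overlap = overlap)
  }
  peak <- sdv <- setNames(rep(NA_real_, length(x)), names(x))
  for (sp in names(x)) {
    recs <- x[[sp]]
    if (inherits(recs, c("waveform", "power_spectrum")) || is.character(recs)) {
      recs <- list(recs)
    }
    specs <- list()
    for (rec in recs) {
      s <- tryCatch(as_spectrum(rec), error = function(e) {
        failures <<- c(failures, paste0(sp, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(s)) specs[[length(specs) + 1L]] <- s
    }
    if (length(specs) == 0) next
    grid <- specs[[1]]$frequencies
    pows <- vapply(specs, function(s) {
      p <- s$power / sum(s$power)
      if (length(s$frequencies) != length(grid) ||
          any(s$frequencies != grid)) {
        p <- stats::approx(s$frequencies, p, xout = grid, rule = 2)$y
      }
      p
    }, numeric(length(grid)))
    avg <- structure(list(frequencies = grid,
                          power = rowMeans(as.matrix(pows)),
                          params = specs[[1]]$params),
                     class = "power_spectrum")
    peak[sp] <- peak_frequency(avg)
    sdv[sp] <- spectrum_sd(avg, db_scale = db_scale)
  }
  ok <- !is.na(peak)
  if (sum(ok) < 2) stop("fewer than 2 species classifiable; failures: ",
                        paste(failures, collapse = "; "))
  het <- classify_heterogeneity(sdv[ok])
  fg <- assign_frequency_group(peak[ok])
  out <- data.frame(species = names(x)[ok], peak_khz = unname(peak[ok]),
                    sd = unname(sdv[ok]), heterogeneity = unname(het),
                    freq_group = fg,
                    group8 = group8_label(fg, unname(het)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
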