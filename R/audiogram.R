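#' Construct an audiogram
#'
#' An audiogram is a tibble of pure-tone hearing thresholds (dB HL) at standard
#' audiometric test frequencies, with an `ear` attribute. It is the input both
#' to inclusion screening and to treatment-sound design.
#'
#' @param frequencies_hz Numeric vector of test frequencies in Hz. Must be a
#'   subset of the standard set 125, 250, 500, 1000, 2000, 4000, 8000, 10000,
#'   12000, 16000, 20000 Hz; rows are sorted into ascending frequency order.
#' @param thresholds_db_hl Numeric vector of thresholds in dB HL, one per
#'   frequency, each in `[-10, 120]`.
#' @param ear One of `"left"`, `"right"`, `"binaural-mean"`.
#' @return A tibble of class `audiogram` with columns `frequency_hz` and
#'   `threshold_db_hl`, ordered by ascending frequency.
#' @examples
#' aud <- audiogram(
#'   frequencies_hz   = c(125, 250, 500, 1000, 2000, 4000, 8000),
#'   thresholds_db_hl = c(10, 15, 20, 30, 35, 45, 45)
#' )
#' check_inclusion(aud)
#' hearing_loss_band(aud)
#' @export
audiogram <- function(frequencies_hz, thresholds_db_hl, ear = c("binaural-mean", "left", "right")) {
  ear <- match.arg(ear)
  if (length(frequencies_hz) != length(thresholds_db_hl)) {
    stop("`frequencies_hz` and `thresholds_db_hl` must have the same length", call. = FALSE)
  }
  if (length(frequencies_hz) < 2) {
    stop("an audiogram needs at least 2 test frequencies", call. = FALSE)
  }
  if (!all(frequencies_hz %in% AUDIOMETRIC_FREQS)) {
    stop("frequencies must be standard audiometric frequencies (125 Hz - 20 kHz)", call. = FALSE)
  }
  if (anyDuplicated(frequencies_hz)) {
    stop("duplicate test frequencies", call. = FALSE)
  }
  if (any(thresholds_db_hl < -10 | thresholds_db_hl > 120)) {
    stop("thresholds must lie in [-10, 120] dB HL", call. = FALSE)
  }
  ord <- order(frequencies_hz)
  out <- tibble::tibble(
    frequency_hz    = as.numeric(frequencies_hz[ord]),
    threshold_db_hl = as.numeric(thresholds_db_hl[ord])
  )
  structure(out, ear = ear, class = c("audiogram", class(out)))
}

#' Read / write an audiogram CSV
#'
#' The on-disk dialect is a two-column, comma-separated, UTF-8 file with a
#' required header `frequency_hz,threshold_db_hl`.
#'
#' @param path File path.
#' @param ear Ear label passed to [audiogram()].
#' @return `read_audiogram()` returns an `audiogram`; `write_audiogram()`
#'   invisibly returns `path`.
#' @export
read_audiogram <- function(path, ear = "binaural-mean") {
  df <- readr::read_csv(path, col_types = readr::cols(
    frequency_hz = readr::col_double(),
    threshold_db_hl = readr::col_double()
  ))
  audiogram(df$frequency_hz, df$threshold_db_hl, ear = ear)
}

#' @rdname read_audiogram
#' @param aud An `audiogram`.
#' @export
write_audiogram <- function(aud, path) {
  stopifnot(inherits(aud, "audiogram"))
  readr::write_csv(tibble::as_tibble(aud), path)
  invisible(path)
}

#' Screen an audiogram against the study inclusion rule
#'
#' Patients whose hearing threshold exceeds 90 dB HL at any test frequency in
#' the 0.125-20 kHz range are excluded, so that the enrichment sound can
#' deliver audible input at every frequency it covers. The bound is strict:
#' a threshold of exactly 90 dB HL is still included.
#'
#' @param aud An `audiogram`.
#' @param max_db_hl Exclusion bound in dB HL (default 90).
#' @return `TRUE` if every threshold is at or below `max_db_hl`.
#' @export
check_inclusion <- function(aud, max_db_hl = 90) {
  stopifnot(inherits(aud, "audiogram"))
  all(aud$threshold_db_hl <= max_db_hl)
}

#' Hearing-loss frequency band of an audiogram
#'
#' The treatment sound spans the patient's hearing-loss frequency range: the
#' contiguous span from the lowest to the highest test frequency whose
#' threshold exceeds `criterion_db` (25 dB HL by default, the usual clinical
#' cut for hearing loss). Interior dips back below the criterion do not split
#' the band. A single qualifying frequency yields a degenerate band, widened
#' to a half octave around that frequency so the passband is usable.
#'
#' @param aud An `audiogram`.
#' @param criterion_db Hearing-loss criterion in dB HL (default 25).
#' @return A `frequency_band`: list with `f_low_hz`, `f_high_hz`.
#' @export
hearing_loss_band <- function(aud, criterion_db = 25) {
  stopifnot(inherits(aud, "audiogram"))
  hit <- which(aud$threshold_db_hl > criterion_db)
  if (length(hit) == 0) {
    stop("no hearing loss: no threshold exceeds ", criterion_db,
         " dB HL; sound enrichment is undefined for this audiogram", call. = FALSE)
  }
  f_lo <- aud$frequency_hz[min(hit)]
  f_hi <- aud$frequency_hz[max(hit)]
  if (f_lo == f_hi) {
    # degenerate one-frequency band: widen to a half octave around it
    f_lo <- f_lo * 2^(-1 / 4)
    f_hi <- f_hi * 2^(1 / 4)
  }
  frequency_band(f_lo, f_hi)
}

#' Construct a frequency band
#'
#' @param f_low_hz,f_high_hz Band edges in Hz, `0 < f_low_hz < f_high_hz`.
#' @return A list of class `frequency_band`.
#' @export
frequency_band <- function(f_low_hz, f_high_hz) {
  if (!(f_low_hz > 0 && f_high_hz > f_low_hz)) {
    stop("need 0 < f_low_hz < f_high_hz", call. = FALSE)
  }
  structure(list(f_low_hz = f_low_hz, f_high_hz = f_high_hz), class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %.6g - %.6g Hz\n", x$f_low_hz, x$f_high_hz))
  invisible(x)
}

#' Filter smoothing parameter from an adjacent-threshold difference
#'
#' The band-pass filter's edge sharpness adapts to the audiogram shape: where
#' adjacent thresholds differ little, a gentle (high) smoothing is used; where
#' hearing loss rises significantly (>= 20 dB between adjacent frequencies) a
#' sharp (low) smoothing is used. The mapping is piecewise linear on the
#' 1-100 smoothing scale:
#'
#' * `d < 20`:  `s = 100 - 2 d`  (so a 10-dB difference gives s = 80, and a
#'   flat configuration gives the maximal s = 100);
#' * `d >= 20`: `s = clamp(round(10 (40 - d) / 20), 1, 10)` — the "low"
#'   smoothing range 1-10 reserved for significant threshold jumps.
#'
#' The result is monotone non-increasing in `d` and always in `[1, 100]`.
#'
#' @param adjacent_diff_db Nonnegative absolute difference between adjacent
#'   hearing thresholds, in dB. Vectorized.
#' @return Integer smoothing parameter(s) in `[1, 100]`.
#' @examples
#' smoothing_parameter(10) # 80
#' smoothing_parameter(0)  # 100
#' @export
smoothing_parameter <- function(adjacent_diff_db) {
  if (any(adjacent_diff_db < 0)) {
    stop("adjacent threshold difference must be nonnegative", call. = FALSE)
  }
  d <- adjacent_diff_db
  s <- ifelse(d < 20,
              100 - 2 * d,
              clamp(round(10 * (40 - d) / 20), 1, 10))
  as.integer(round(s))
}

#' Edge smoothings for each adjacent-frequency pair inside a band
#'
#' For every pair of adjacent audiogram frequencies inside the hearing-loss
#' band, computes the smoothing parameter from the absolute threshold
#' difference and keys it to the pair's upper frequency. The first and last
#' rows govern the low- and high-edge skirts of the band-pass filter.
#'
#' @param aud An `audiogram`.
#' @param band A `frequency_band` derived from `aud`.
#' @return A tibble with columns `boundary_hz`, `diff_db`, `s`.
#' @export
edge_smoothings <- function(aud, band) {
  stopifnot(inherits(aud, "audiogram"), inherits(band, "frequency_band"))
  if (band$f_low_hz < min(aud$frequency_hz) / 2^(1 / 4) ||
      band$f_high_hz > max(aud$frequency_hz) * 2^(1 / 4)) {
    stop("band lies outside the audiogram's frequency range", call. = FALSE)
  }
  inside <- dplyr::filter(tibble::as_tibble(aud),
                          .data$frequency_hz >= band$f_low_hz,
                          .data$frequency_hz <= band$f_high_hz)
  if (nrow(inside) < 2) {
    # degenerate (widened single-frequency) band: one maximal-smoothness edge
    return(tibble::tibble(boundary_hz = band$f_high_hz, diff_db = 0, s = 100L))
  }
  d <- abs(diff(inside$threshold_db_hl))
  tibble::tibble(
    boundary_hz = inside$frequency_hz[-1],
    diff_db     = d,
    s           = smoothing_parameter(d)
  )
}

#' Plot an audiogram
#'
#' Clinical convention: frequency on a log axis, threshold increasing
#' downwards.
#'
#' @param object An `audiogram`.
#' @param criterion_db Optional hearing-loss criterion drawn as a reference
#'   line (default 25 dB HL).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot audiogram
#' @export
autoplot.audiogram <- function(object, criterion_db = 25, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency_hz, y = .data$threshold_db_hl)) +
    ggplot2::geom_hline(yintercept = criterion_db, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 1, size = 3) +
    ggplot2::scale_x_log10(breaks = AUDIOMETRIC_FREQS,
                           labels = function(f) ifelse(f >= 1000, paste0(f / 1000, "k"), f)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Threshold (dB HL)",
                  title = paste0("Audiogram (", attr(object, "ear"), ")")) +
    ggplot2::theme_minimal()
}
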