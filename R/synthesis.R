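#' Noise synthesis specification
#'
#' @param fs_hz Sample rate in Hz (default 44100, the rate used for treatment
#'   sounds).
#' @param duration_s Duration in seconds (> 0; default 60).
#' @param seed Integer RNG seed; the same spec always yields the same noise.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(fs_hz = 44100, duration_s = 60, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  structure(list(fs_hz = fs_hz, duration_s = duration_s, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Construct a sound complex
#'
#' A sampled waveform plus its sample rate and a provenance tag recording
#' which synthesis stage produced it: `v1` (audiogram-shaped noise), `v2`
#' (tinnitus-pitch band noise), `v3` (the combined treatment sound) or `raw`.
#'
#' @param samples Numeric vector of finite samples.
#' @param fs_hz Sample rate in Hz.
#' @param provenance One of `"raw"`, `"v1"`, `"v2"`, `"v3"`.
#' @return A list of class `sound_complex`.
#' @export
sound_complex <- function(samples, fs_hz, provenance = "raw") {
  provenance <- match.arg(provenance, c("raw", "v1", "v2", "v3"))
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, provenance = provenance),
            class = "sound_complex")
}

#' @export
print.sound_complex <- function(x, ...) {
  cat(sprintf("<sound_complex %s> %d samples @ %g Hz (%.3g s), peak %.3f\n",
              x$provenance, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, max(abs(x$samples))))
  invisible(x)
}

#' Generate seeded Gaussian white noise
#'
#' The raw material for every treatment sound: i.i.d. zero-mean, unit-variance
#' Gaussian samples, reproducible from the spec's seed.
#'
#' @param spec A [noise_spec()].
#' @return A `sound_complex` with provenance `"raw"`.
#' @export
generate_white_noise <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- round(spec$fs_hz * spec$duration_s)
  x <- withr::with_seed(spec$seed, stats::rnorm(n))
  sound_complex(x, spec$fs_hz, "raw")
}

# Frequency-domain gain application: builds the two-sided gain from a
# function of nonnegative frequency and returns the filtered real signal.
apply_fd_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  g <- gain_fun(abs(f))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# Raised-cosine (Hann-shaped) band-pass gain in log2 frequency.
# Transition width on each side = (s/100) * (1/3) octave.
bandpass_gain <- function(f, f_lo, f_hi, s_low = 100, s_high = 100) {
  w_lo <- (s_low / 100) / 3
  w_hi <- (s_high / 100) / 3
  g <- numeric(length(f))
  pos <- f > 0
  lf <- log2(pmax(f, .Machine$double.eps))
  inband <- pos & f >= f_lo & f <= f_hi
  g[inband] <- 1
  lo_skirt <- pos & f < f_lo & lf > log2(f_lo) - w_lo
  g[lo_skirt] <- cos(pi / 2 * (log2(f_lo) - lf[lo_skirt]) / w_lo)^2
  hi_skirt <- pos & f > f_hi & lf < log2(f_hi) + w_hi
  g[hi_skirt] <- cos(pi / 2 * (lf[hi_skirt] - log2(f_hi)) / w_hi)^2
  g
}

#' Band-pass filter a sound complex
#'
#' Frequency-domain filter with unity gain inside the band and raised-cosine
#' (Hann-shaped) skirts in log-frequency. The transition width on each side is
#' `(s/100) * 1/3` octave, so the smoothing parameter `s` in `[1, 100]` maps
#' a sharp (1/300 octave) to a gentle (1/3 octave) edge. Beyond one transition
#' width outside the band the gain is exactly zero.
#'
#' @param sound A `sound_complex`.
#' @param band A `frequency_band`; the upper edge must lie below Nyquist.
#' @param s_low,s_high Smoothing parameters in `[1, 100]` for the low and high
#'   skirts (see [smoothing_parameter()]).
#' @return A filtered `sound_complex` (provenance preserved).
#' @export
bandpass <- function(sound, band, s_low = 100, s_high = 100) {
  stopifnot(inherits(sound, "sound_complex"), inherits(band, "frequency_band"))
  if (band$f_high_hz >= sound$fs_hz / 2) {
    stop("band edge at or above Nyquist frequency", call. = FALSE)
  }
  y <- apply_fd_gain(sound$samples, sound$fs_hz, function(f) {
    bandpass_gain(f, band$f_low_hz, band$f_high_hz, s_low, s_high)
  })
  out <- sound_complex(y, sound$fs_hz, sound$provenance)
  attr(out, "band") <- band
  out
}

#' Shape band-limited noise to an audiogram (sound complex v1)
#'
#' Applies a per-frequency gain so the amplitude envelope of the noise follows
#' the hearing-loss configuration: gain in dB at frequency f equals
#' `threshold(f) - criterion_db`, linearly interpolated in log-frequency
#' between audiogram points (constant beyond the outermost points). Deeper
#' hearing loss therefore receives proportionally more energy.
#'
#' @param sound A band-passed `sound_complex` (see [bandpass()]).
#' @param aud The `audiogram` the band was derived from.
#' @param band The `frequency_band` returned by [hearing_loss_band()].
#' @param criterion_db Hearing-loss criterion used for the band (default 25).
#' @return A `sound_complex` with provenance `"v1"`.
#' @export
shape_to_audiogram <- function(sound, aud, band, criterion_db = 25) {
  stopifnot(inherits(sound, "sound_complex"), inherits(aud, "audiogram"),
            inherits(band, "frequency_band"))
  if (band$f_low_hz > max(aud$frequency_hz) || band$f_high_hz < min(aud$frequency_hz)) {
    stop("band does not overlap the audiogram's frequency range", call. = FALSE)
  }
  lf_knots <- log2(aud$frequency_hz)
  gain_db_knots <- aud$threshold_db_hl - criterion_db
  y <- apply_fd_gain(sound$samples, sound$fs_hz, function(f) {
    g_db <- stats::approx(lf_knots, gain_db_knots,
                          xout = log2(pmax(f, .Machine$double.eps)),
                          rule = 2)$y
    10^(g_db / 20)
  })
  out <- sound_complex(y, sound$fs_hz, "v1")
  attr(out, "band") <- band
  out
}

#' Tinnitus-pitch band edges
#'
#' The amplification band around a matched tinnitus pitch extends 10% below
#' and 10% above the pitch.
#'
#' @param pitch_hz Tinnitus pitch-match frequency in Hz.
#' @return A `frequency_band` `(0.9 * pitch, 1.1 * pitch)`.
#' @examples
#' tinnitus_band_range(6000) # 5400 - 6600 Hz
#' @export
tinnitus_band_range <- function(pitch_hz) {
  if (pitch_hz <= 0) stop("pitch must be positive", call. = FALSE)
  frequency_band(0.9 * pitch_hz, 1.1 * pitch_hz)
}

#' Tinnitus-pitch band noise (sound complex v2)
#'
#' Fresh white noise band-pass filtered to 10% below and above the tinnitus
#' pitch. The in-band amplitude profile is a raised-cosine bump (in
#' log-frequency) peaked exactly at the pitch and falling to zero at the
#' band edges, so the component's spectral maximum sits at the tinnitus
#' pitch itself rather than anywhere within a flat passband. This component
#' concentrates energy where tinnitus-related spontaneous activity is
#' assumed highest.
#'
#' @param pitch_hz Tinnitus pitch in Hz; `1.1 * pitch_hz` must lie below
#'   Nyquist.
#' @param spec A [noise_spec()].
#' @return A `sound_complex` with provenance `"v2"` and a `band` attribute
#'   holding the `(0.9 p, 1.1 p)` band.
#' @export
tinnitus_band <- function(pitch_hz, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  band <- tinnitus_band_range(pitch_hz)
  if (band$f_high_hz >= spec$fs_hz / 2) {
    stop("tinnitus pitch too high for this sample rate", call. = FALSE)
  }
  noise <- generate_white_noise(noise_spec(spec$fs_hz, spec$duration_s,
                                           sub_seed(spec$seed, "v2")))
  w <- log2(1.1)                       # half-width of the band in octaves
  y <- apply_fd_gain(noise$samples, noise$fs_hz, function(f) {
    d <- abs(log2(pmax(f, .Machine$double.eps) / pitch_hz))
    ifelse(f > 0 & d < w, cos(pi / 2 * d / w)^2, 0)
  })
  out <- sound_complex(y, spec$fs_hz, "v2")
  attr(out, "band") <- band
  out
}

#' Mix the audiogram-shaped and tinnitus-band components (sound complex v3)
#'
#' Combines v1 and v2 in mono: `v3 = v1 + g * v2`, with the gain `g` chosen so
#' that the band-averaged power inside the tinnitus band exceeds the v1-only
#' level there by `boost_db`. The result is peak-normalized to -1 dBFS, giving
#' the individualized treatment sound whose spectrum spans the hearing-loss
#' range and peaks at the tinnitus pitch.
#'
#' @param v1 `sound_complex` from [shape_to_audiogram()].
#' @param v2 `sound_complex` from [tinnitus_band()] (carries the tinnitus
#'   band attribute).
#' @param boost_db Target tinnitus-band boost in dB (default +6).
#' @return A `sound_complex` with provenance `"v3"`.
#' @export
mix_v3 <- function(v1, v2, boost_db = 6) {
  stopifnot(inherits(v1, "sound_complex"), inherits(v2, "sound_complex"))
  if (v1$fs_hz != v2$fs_hz || length(v1$samples) != length(v2$samples)) {
    stop("v1 and v2 must share sample rate and length", call. = FALSE)
  }
  band <- attr(v2, "band")
  if (is.null(band)) stop("v2 carries no tinnitus band attribute", call. = FALSE)
  p1 <- band_power(welch_psd(v1), band)
  p2 <- band_power(welch_psd(v2), band)
  if (p2 <= 0) {
    y <- v1$samples
  } else {
    g <- sqrt(p1 * (10^(boost_db / 10) - 1) / p2)
    y <- v1$samples + g * v2$samples
  }
  y <- y / max(abs(y)) * 10^(-1 / 20)    # peak-normalize to -1 dBFS
  out <- sound_complex(y, v1$fs_hz, "v3")
  attr(out, "band") <- attr(v1, "band")
  attr(out, "tinnitus_band") <- band
  out
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram, scaled so that
#' the PSD integrates to the waveform variance (one-sided density, Parseval
#' consistent).
#'
#' @param sound A `sound_complex`.
#' @param nfft Segment length in samples (default 4096).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `frequency_hz`, `psd`.
#' @export
welch_psd <- function(sound, nfft = 4096, overlap = 0.5) {
  stopifnot(inherits(sound, "sound_complex"))
  x <- sound$samples
  fs <- sound$fs_hz
  nfft <- min(nfft, length(x))
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, length(x) - nfft + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)   # Hann
  scale <- fs * sum(w^2)
  nkeep <- floor(nfft / 2) + 1
  acc <- numeric(nkeep)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nfft - 1)] * w
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[seq_len(nkeep)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, nkeep); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nkeep] <- 1
  tibble::tibble(frequency_hz = (seq_len(nkeep) - 1) * fs / nfft,
                 psd = psd * dbl)
}

#' Band-averaged power from a PSD table
#'
#' @param psd Tibble from [welch_psd()].
#' @param band A `frequency_band`.
#' @return Mean PSD (power density) inside the band.
#' @export
band_power <- function(psd, band) {
  sel <- psd$frequency_hz >= band$f_low_hz & psd$frequency_hz <= band$f_high_hz
  if (!any(sel)) stop("no PSD bins inside band", call. = FALSE)
  mean(psd$psd[sel])
}

#' Spectrum report for a treatment sound
#'
#' Validates a synthesized sound against its design: estimates the Welch PSD,
#' locates the PSD peak, and measures the stop-band attenuation (in-band mean
#' PSD over the mean PSD beyond one transition width outside the hearing-loss
#' band).
#'
#' @param sound A `sound_complex` (typically v3).
#' @param band The hearing-loss `frequency_band`.
#' @param tinnitus_band Optional tinnitus `frequency_band` for peak
#'   validation.
#' @param transition_octaves Skirt width assumed when measuring the stop band
#'   (default 1/3 octave, the widest skirt the filter can produce).
#' @return A list of class `spectrum_report`: `psd` (tibble), `peak_hz`,
#'   `band_attenuation_db`, `peak_in_tinnitus_band` (logical or NA).
#' @export
spectrum_report <- function(sound, band, tinnitus_band = NULL,
                            transition_octaves = 1 / 3) {
  psd <- welch_psd(sound)
  peak_hz <- psd$frequency_hz[which.max(psd$psd)]
  inb <- band_power(psd, band)
  out_sel <- (psd$frequency_hz > 0 &
                psd$frequency_hz < band$f_low_hz * 2^(-transition_octaves)) |
    psd$frequency_hz > band$f_high_hz * 2^(transition_octaves)
  atten_db <- if (any(out_sel)) {
    10 * log10(inb / max(mean(psd$psd[out_sel]), .Machine$double.xmin))
  } else NA_real_
  structure(list(
    psd = psd,
    peak_hz = peak_hz,
    band_attenuation_db = atten_db,
    peak_in_tinnitus_band = if (is.null(tinnitus_band)) NA else
      peak_hz >= tinnitus_band$f_low_hz & peak_hz <= tinnitus_band$f_high_hz
  ), class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report> PSD peak at %.0f Hz; stop-band attenuation %.1f dB\n",
              x$peak_hz, x$band_attenuation_db))
  invisible(x)
}

#' Plot a spectrum report
#'
#' @param object A `spectrum_report`.
#' @param ... Unused.
#' @return A ggplot object (PSD in dB over log frequency).
#' @method autoplot spectrum_report
#' @export
autoplot.spectrum_report <- function(object, ...) {
  df <- dplyr::filter(object$psd, .data$frequency_hz > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz,
                                   y = 10 * log10(pmax(.data$psd, 1e-20)))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_hz, linetype = 2, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB/Hz)",
                  title = "Treatment-sound spectrum") +
    ggplot2::theme_minimal()
}

#' Synthesize an individualized treatment sound
#'
#' Full synthesis chain: inclusion screening, hearing-loss band extraction,
#' audiogram-adaptive edge smoothing, band-passed and audiogram-shaped noise
#' (v1), tinnitus-pitch band noise (v2), and the mono mix (v3) peak-normalized
#' to -1 dBFS with a 50-ms loop crossfade. The accompanying spectrum report
#' verifies that the spectral support matches the hearing-loss band and that
#' the PSD peaks inside the tinnitus band.
#'
#' @param aud An `audiogram` passing [check_inclusion()].
#' @param pitch_hz Tinnitus pitch-match frequency in Hz.
#' @param spec A [noise_spec()].
#' @param criterion_db Hearing-loss criterion in dB HL (default 25).
#' @param boost_db Margin (dB) by which the tinnitus band must top the rest
#'   of the spectrum (default +6). Because the audiogram envelope can place
#'   considerable energy away from the tinnitus pitch, the v2 gain is set
#'   relative to the envelope's maximum: the realized in-band boost over v1
#'   is `boost_db` plus the envelope's peak-over-band margin, which
#'   guarantees the global spectral peak falls at the tinnitus pitch.
#' @return A list with elements `sound` (`sound_complex`, provenance v3) and
#'   `report` (`spectrum_report`).
#' @export
synthesize_treatment_sound <- function(aud, pitch_hz, spec = noise_spec(),
                                       criterion_db = 25, boost_db = 6) {
  if (!check_inclusion(aud)) {
    stop("audiogram fails inclusion screening (threshold > 90 dB HL)", call. = FALSE)
  }
  band <- hearing_loss_band(aud, criterion_db)
  sm <- edge_smoothings(aud, band)
  noise <- generate_white_noise(noise_spec(spec$fs_hz, spec$duration_s,
                                           sub_seed(spec$seed, "v1")))
  bp <- bandpass(noise, band,
                 s_low = sm$s[1], s_high = sm$s[nrow(sm)])
  v1 <- shape_to_audiogram(bp, aud, band, criterion_db)
  v2 <- tinnitus_band(pitch_hz, spec)
  # design-envelope margin: how far the loudest part of the v1 envelope sits
  # above the envelope level inside the tinnitus band (analytic, noise-free)
  fgrid <- 2^seq(log2(band$f_low_hz), log2(band$f_high_hz), length.out = 256)
  env_db <- stats::approx(log2(aud$frequency_hz),
                          aud$threshold_db_hl - criterion_db,
                          xout = log2(fgrid), rule = 2)$y
  tb <- tinnitus_band_range(pitch_hz)
  in_tb <- fgrid >= tb$f_low_hz & fgrid <= tb$f_high_hz
  env_tb <- if (any(in_tb)) mean(env_db[in_tb]) else {
    stats::approx(log2(aud$frequency_hz), aud$threshold_db_hl - criterion_db,
                  xout = log2(clamp(pitch_hz, band$f_low_hz, band$f_high_hz)),
                  rule = 2)$y
  }
  margin_db <- max(env_db) - env_tb
  v3 <- mix_v3(v1, v2, boost_db = margin_db + boost_db)
  v3$samples <- loop_crossfade(v3$samples, v3$fs_hz)
  rep <- spectrum_report(v3, band, tinnitus_band = attr(v3, "tinnitus_band"))
  list(sound = v3, report = rep)
}

# Crossfade the last `fade_s` seconds into the head so the sound loops
# seamlessly.
loop_crossfade <- function(x, fs, fade_s = 0.05) {
  L <- round(fs * fade_s)
  n <- length(x)
  if (L < 2 || 2 * L > n) return(x)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = L)))  # 0 -> 1
  tail_idx <- (n - L + 1):n
  x[tail_idx] <- x[tail_idx] * rev(ramp) + x[1:L] * ramp
  x
}
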