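# Short durations keep spectral estimates cheap; 1-2 s at 44.1 kHz is ample
# for Welch averaging with 4096-sample segments.

test_that("white noise generation is seeded, Gaussian, and sized fs x duration", {
  spec <- noise_spec(44100, 1.0, seed = 1)
  wn <- generate_white_noise(spec)
  expect_length(wn$samples, 44100)
  expect_identical(wn$samples, generate_white_noise(spec)$samples)

  n <- length(wn$samples)
  expect_lt(abs(mean(wn$samples)), 4 / sqrt(n))
  expect_lt(abs(var(wn$samples) - 1), 5 * sqrt(2 / n))
  expect_error(noise_spec(44100, 0), "positive")
})

test_that("bandpass is unity in-band and attenuates >= 40 dB beyond the skirt", {
  t <- seq_len(44100) / 44100
  band <- frequency_band(5400, 6600)
  tone_in <- sound_complex(sin(2 * pi * 6000 * t), 44100)
  tone_out <- sound_complex(sin(2 * pi * 1000 * t), 44100)
  y_in <- bandpass(tone_in, band)
  y_out <- bandpass(tone_out, band)
  expect_equal(rms(y_in$samples) / rms(tone_in$samples), 1, tolerance = 1e-3)
  expect_lt(20 * log10(rms(y_out$samples) / rms(tone_out$samples)), -40)
  expect_error(bandpass(tone_in, frequency_band(1000, 23000)), "Nyquist")
})

test_that("band-passed noise concentrates its PSD support in the band", {
  wn <- generate_white_noise(noise_spec(44100, 2, seed = 3))
  y <- bandpass(wn, frequency_band(1000, 8000))
  psd <- welch_psd(y)
  inband <- band_power(psd, frequency_band(1000, 8000))
  below <- band_power(psd, frequency_band(100, 700))
  above <- band_power(psd, frequency_band(11000, 20000))
  expect_gt(10 * log10(inband / below), 40)
  expect_gt(10 * log10(inband / above), 40)
})

test_that("bandpass is idempotent in the passband (< 0.5 dB RMS change)", {
  wn <- generate_white_noise(noise_spec(44100, 1, seed = 4))
  band <- frequency_band(1000, 8000)
  once <- bandpass(wn, band, s_low = 80, s_high = 80)
  twice <- bandpass(once, band, s_low = 80, s_high = 80)
  core <- frequency_band(1100, 7000)   # fully inside the passband
  p1 <- band_power(welch_psd(once), core)
  p2 <- band_power(welch_psd(twice), core)
  expect_lt(abs(10 * log10(p2 / p1)), 0.5)
})

test_that("Welch PSD is Parseval-consistent with waveform variance", {
  wn <- generate_white_noise(noise_spec(44100, 2, seed = 5))
  psd <- welch_psd(wn)
  df <- psd$frequency_hz[2] - psd$frequency_hz[1]
  expect_equal(sum(psd$psd) * df, var(wn$samples), tolerance = 0.01)
})

test_that("audiogram shaping reproduces the threshold-minus-criterion envelope", {
  # flat 40 dB loss -> spectrally flat v1 within the band
  flat <- audiogram(c(500, 1000, 2000, 4000, 8000), c(10, 40, 40, 40, 40))
  bf <- hearing_loss_band(flat)
  wn <- generate_white_noise(noise_spec(44100, 2, seed = 6))
  v1f <- shape_to_audiogram(bandpass(wn, bf), flat, bf)
  expect_identical(v1f$provenance, "v1")
  psd <- welch_psd(v1f)
  lo <- band_power(psd, frequency_band(1500, 2500))
  hi <- band_power(psd, frequency_band(4000, 7000))
  expect_lt(abs(10 * log10(hi / lo)), 1)

  # rising 30 -> 50 dB loss from 1 to 8 kHz: ~20 dB PSD tilt
  rise <- audiogram(c(125, 250, 500, 1000, 2000, 4000, 8000),
                    c(10, 10, 20, 30, 37, 44, 50))
  br <- hearing_loss_band(rise)
  v1r <- shape_to_audiogram(bandpass(wn, br), rise, br)
  psd_r <- welch_psd(v1r)
  at1k <- band_power(psd_r, frequency_band(1000, 1100))
  at8k <- band_power(psd_r, frequency_band(7300, 7900))
  expect_equal(10 * log10(at8k / at1k), 20, tolerance = 2)
})

test_that("tinnitus band arithmetic and v2 spectral peak", {
  b6 <- tinnitus_band_range(6000)
  expect_equal(b6$f_low_hz, 5400)
  expect_equal(b6$f_high_hz, 6600)
  b1 <- tinnitus_band_range(1000)
  expect_equal(c(b1$f_low_hz, b1$f_high_hz), c(900, 1100))

  v2 <- tinnitus_band(6000, noise_spec(44100, 2, seed = 7))
  expect_identical(v2$provenance, "v2")
  psd <- welch_psd(v2)
  peak <- psd$frequency_hz[which.max(psd$psd)]
  expect_gt(peak, 5400)
  expect_lt(peak, 6600)
  expect_error(tinnitus_band(21000, noise_spec(44100, 1)), "too high")
})

test_that("v3 mix places the configured boost in the tinnitus band", {
  aud <- example_audiogram()
  band <- hearing_loss_band(aud)
  wn <- generate_white_noise(noise_spec(44100, 2, seed = 8))
  v1 <- shape_to_audiogram(bandpass(wn, band), aud, band)
  v2 <- tinnitus_band(6000, noise_spec(44100, 2, seed = 8))
  v3 <- mix_v3(v1, v2, boost_db = 6)
  expect_identical(v3$provenance, "v3")
  expect_equal(max(abs(v3$samples)), 10^(-1 / 20), tolerance = 1e-9)

  # boost measured scale-invariantly: tinnitus-band level relative to a
  # reference band, v3 vs v1
  tb <- attr(v3, "tinnitus_band")
  ref <- frequency_band(1500, 3000)
  p3 <- welch_psd(v3); p1 <- welch_psd(v1)
  boost <- 10 * log10(band_power(p3, tb) / band_power(p3, ref)) -
    10 * log10(band_power(p1, tb) / band_power(p1, ref))
  expect_equal(boost, 6, tolerance = 1)

  # silent v2 -> v3 proportional to v1
  v2s <- v2; v2s$samples <- numeric(length(v2$samples))
  attr(v2s, "band") <- attr(v2, "band")
  v3s <- mix_v3(v1, v2s)
  expect_equal(stats::cor(v3s$samples, v1$samples), 1, tolerance = 1e-12)
  expect_error(mix_v3(v1, sound_complex(1:10 / 10, 44100)), "length|band")
})

test_that("full synthesis chain validates support, peak and determinism", {
  aud <- example_audiogram()
  out <- synthesize_treatment_sound(aud, 6000, noise_spec(44100, 2, seed = 5))
  expect_true(out$report$peak_in_tinnitus_band)
  expect_gt(out$report$band_attenuation_db, 40)
  expect_gt(out$report$peak_hz, 5400)
  expect_lt(out$report$peak_hz, 6600)

  bad <- audiogram(c(125, 500, 2000, 8000), c(10, 30, 45, 95))
  expect_error(synthesize_treatment_sound(bad, 6000), "inclusion")

  out2 <- synthesize_treatment_sound(aud, 6000, noise_spec(44100, 2, seed = 5))
  expect_identical(out$sound$samples, out2$sound$samples)
})

test_that("v3 PSD peaks inside the tinnitus band across randomized audiograms", {
  # property: over randomized sloping-loss audiograms and pitches, the
  # treatment sound's global PSD maximum falls in (0.9 p, 1.1 p)
  withr::with_seed(99, {
    for (i in 1:12) {
      thr <- cummax(sort(sample(seq(10, 70, 5), 7, replace = TRUE)))
      aud <- audiogram(c(125, 250, 500, 1000, 2000, 4000, 8000), thr)
      if (!any(thr > 25)) next
      band <- hearing_loss_band(aud)
      pitch <- exp(runif(1, log(max(1200, band$f_low_hz)),
                         log(min(7000, band$f_high_hz))))
      out <- synthesize_treatment_sound(aud, pitch, noise_spec(44100, 1, seed = i))
      expect_gt(out$report$peak_hz, 0.9 * pitch)
      expect_lt(out$report$peak_hz, 1.1 * pitch)
    }
  })
})

test_that("WAV output round-trips 16-bit PCM mono and is byte-stable", {
  aud <- example_audiogram()
  out <- synthesize_treatment_sound(aud, 6000, noise_spec(44100, 0.5, seed = 2))
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(out$sound, p1)
  write_wav(synthesize_treatment_sound(aud, 6000, noise_spec(44100, 0.5, seed = 2))$sound, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_wav(p1)
  expect_equal(back$fs_hz, 44100)
  expect_lt(max(abs(back$samples - out$sound$samples)), 1 / 32767)
})
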