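# internal helpers shared across modules

# Standard audiometric test frequencies (Hz) used throughout.
AUDIOMETRIC_FREQS <- c(125, 250, 500, 1000, 2000, 4000, 8000, 10000, 12000, 16000, 20000)

#' Derive a reproducible sub-seed from a root seed
#'
#' All stochastic stages (cohort draws, subject resolution, listener responses,
#' noise synthesis) derive their own stream from one root seed via a named
#' offset, so each stage is independently reproducible.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
sub_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (abs(as.numeric(seed)) * 2654435 + offs) %% 2147483629
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Snap to a grid with given step (e.g. the 5-dB audiometer grid).
round_to_grid <- function(x, step) round(x / step) * step

`%||%` <- function(a, b) if (is.null(a)) b else a
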