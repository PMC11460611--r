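# Shared fixtures, built in code.

# Sloping-loss audiogram whose hearing-loss range is 1-8 kHz and whose
# 1-2 kHz threshold step is 10 dB.
example_audiogram <- function() {
  audiogram(
    frequencies_hz   = c(125, 250, 500, 1000, 2000, 4000, 8000),
    thresholds_db_hl = c(10, 15, 20, 30, 40, 50, 55)
  )
}

# Small balanced split-plot dataset: n_a + n_b subjects, 4 timepoints,
# additive group and time effects plus noise.
toy_mixed_data <- function(n_a = 5, n_b = 3, seed = 42) {
  withr::with_seed(seed, {
    d <- expand.grid(subject_id = sprintf("s%d", seq_len(n_a + n_b)),
                     time = c("pre", "m1", "m3", "m6"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= n_a, "A", "B")
    d$value <- stats::rnorm(nrow(d)) +
      0.5 * as.integer(factor(d$time, levels = c("pre", "m1", "m3", "m6"))) +
      1.0 * (d$group == "A")
    tibble::as_tibble(d)
  })
}

# One-outcome cohort config, optionally under the null (both groups share
# the same flat cell means).
single_outcome_config <- function(outcome = "tll", null = FALSE, seed = 1,
                                  rho = 0.5, n_resolved_pos = 0) {
  p <- dplyr::filter(tinnisim:::default_outcome_params(), outcome == !!outcome)
  if (null) {
    p$mean <- 6
    p$sd <- 1.5
    p$outcome <- "vas_severity"
  }
  cohort_config(outcome_params = p, n_resolved_pos = n_resolved_pos,
                rho = rho, seed = seed)
}

rms <- function(x) sqrt(mean(x^2))
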