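#' Half-octave pitch-matching grid
#'
#' Candidate frequencies for tinnitus pitch matching: half-octave steps
#' anchored at 125 Hz, up to the last step below the 20 kHz test ceiling
#' (16 kHz).
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
pitch_grid <- function() 125 * 2^(seq(0, 7, by = 0.5))

#' Construct a virtual listener
#'
#' A minimal psychophysical observer standing in for a study participant: it
#' holds the ground-truth tinnitus percept and responds to forced-choice
#' trials by picking the option closest to the (noise-corrupted) truth, with a
#' lapse probability of responding at random.
#'
#' @param true_pitch_hz Ground-truth tinnitus pitch in Hz.
#' @param true_loudness_db_sl Ground-truth tinnitus loudness in dB SL.
#' @param true_masking_db Ground-truth minimum masking level in dB.
#' @param ri_positive Logical: does masking produce residual inhibition?
#' @param thresholds Optional `audiogram` carried as metadata.
#' @param lapse_prob Probability in `[0, 1]` of a uniformly random response on
#'   any trial (default 0).
#' @param comparison_noise_db SD (dB) of the Gaussian internal noise on level
#'   comparisons; pitch comparisons use `comparison_noise_db / 20` octaves
#'   (default 0 = ideal observer).
#' @param tinnitus_present Logical; `FALSE` models a resolved tinnitus, for
#'   which loudness and masking procedures return 0 by convention.
#' @return A list of class `virtual_listener`.
#' @export
virtual_listener <- function(true_pitch_hz, true_loudness_db_sl, true_masking_db,
                             ri_positive, thresholds = NULL,
                             lapse_prob = 0, comparison_noise_db = 0,
                             tinnitus_present = TRUE) {
  stopifnot(lapse_prob >= 0, lapse_prob <= 1, comparison_noise_db >= 0)
  structure(list(
    true_pitch_hz = true_pitch_hz,
    true_loudness_db_sl = true_loudness_db_sl,
    true_masking_db = true_masking_db,
    ri_positive = isTRUE(ri_positive),
    thresholds = thresholds,
    lapse_prob = lapse_prob,
    comparison_noise_db = comparison_noise_db,
    tinnitus_present = isTRUE(tinnitus_present)
  ), class = "virtual_listener")
}

# 2AFC decision: TRUE if the listener picks `b` over the incumbent `a`.
# Exact ties go to the newly proposed alternative `b` (the adaptive track
# keeps moving on a tie). `truth` and candidates are on a common scale
# (log2 Hz for pitch, dB for level).
choose_alternative <- function(truth, a, b, noise_sd, lapse_prob) {
  if (lapse_prob > 0 && stats::runif(1) < lapse_prob) {
    return(stats::runif(1) < 0.5)
  }
  t_noisy <- truth + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  abs(b - t_noisy) <= abs(a - t_noisy)
}

MAX_TRIALS <- 200L

#' Tinnitus pitch matching by adaptive two-alternative forced choice
#'
#' Reproduces the clinical procedure: the first pair is 0.5/4 kHz; the next
#' pair pits the chosen frequency against the frequency one octave further in
#' the chosen direction; once the direction reverses (or the grid boundary is
#' reached) the search continues in half-octave increments around the current
#' candidate, alternating sides. The match is the first frequency chosen three
#' times during the half-octave stage: the coarse octave stage only locates
#' the neighborhood, so its choices do not count toward termination (counting
#' them would let the staircase stop at an octave frequency before the
#' half-octave neighbors have ever been offered). Contralateral presentation
#' at 30 dB SL is recorded in the trace as metadata; it does not influence
#' the simulated decision.
#'
#' @param listener A `virtual_listener` with tinnitus present.
#' @param seed Integer seed for the listener's response noise.
#' @return A list with `pitch_hz` (the matched frequency) and `trace`
#'   (a tibble of trials: `trial`, `f1_hz`, `f2_hz`, `choice_hz`).
#' @export
pitch_match <- function(listener, seed = 1L) {
  stopifnot(inherits(listener, "virtual_listener"))
  if (!listener$tinnitus_present) stop("listener has no tinnitus to match", call. = FALSE)
  grid <- pitch_grid()
  noise_oct <- listener$comparison_noise_db / 20
  lt <- log2(listener$true_pitch_hz)

  K <- length(grid)
  withr::with_seed(sub_seed(seed, "pitch"), {
    counts <- integer(K)
    steps <- vector("list", MAX_TRIALS)
    cur <- which(grid == 500)              # grid indices; first pair 0.5 / 4 kHz
    alt <- which(grid == 4000)
    phase <- "octave"; dir <- 0L; side <- +1L
    for (trial in seq_len(MAX_TRIALS)) {
      pick_alt <- choose_alternative(lt, log2(grid[cur]), log2(grid[alt]),
                                     noise_oct, listener$lapse_prob)
      choice <- if (pick_alt) alt else cur
      steps[[trial]] <- tibble::tibble(trial = trial,
                                       f1_hz = grid[min(cur, alt)],
                                       f2_hz = grid[max(cur, alt)],
                                       choice_hz = grid[choice])
      if (phase == "half") counts[choice] <- counts[choice] + 1L
      if (counts[choice] >= 3L) {
        trace <- dplyr::bind_rows(steps[seq_len(trial)])
        attr(trace, "contralateral_db_sl") <- 30
        return(list(pitch_hz = grid[choice], trace = trace))
      }
      if (phase == "octave") {
        if (trial == 1L) {
          dir <- if (choice == max(cur, alt)) +2L else -2L   # one octave = 2 steps
        } else if (!pick_alt) {
          phase <- "half"                  # direction reversed: refine backwards
          side <- -sign(dir)
        }
        cur <- choice
        if (phase == "octave") {
          proposal <- cur + dir
          if (proposal >= 1L && proposal <= K) {
            alt <- proposal
            next
          }
          phase <- "half"                  # grid boundary reached
        }
      } else {
        cur <- choice
      }
      # half-octave refinement, alternating sides around the candidate
      repeat {
        proposal <- cur + side
        side <- -side
        if (proposal >= 1L && proposal <= K) break
      }
      alt <- proposal
    }
  })
  stop("pitch match did not converge within ", MAX_TRIALS, " trials", call. = FALSE)
}

#' Tinnitus loudness level by ascending 2AFC in 5-dB steps
#'
#' Starting from a pair at threshold (0 dB SL) and 5 dB SL, the listener
#' repeatedly picks the tone closer in loudness to the tinnitus; the pair then
#' advances in 5-dB sensation-level steps. The tinnitus loudness level (TLL)
#' is the first level chosen three times; 0 dB SL (tinnitus at threshold) is a
#' valid outcome. Listeners whose tinnitus has resolved return 0 by the
#' study's convention.
#'
#' @param listener A `virtual_listener`.
#' @param pitch_hz Pitch-match frequency used for the tone (metadata).
#' @param seed Integer seed for response noise.
#' @return A list with `tll_db_sl` and `trace`.
#' @export
loudness_match <- function(listener, pitch_hz = listener$true_pitch_hz, seed = 1L) {
  stopifnot(inherits(listener, "virtual_listener"))
  if (!listener$tinnitus_present) {
    trace <- tibble::tibble(trial = 1L, level1_db_sl = NA_real_,
                            level2_db_sl = NA_real_, choice_db_sl = 0,
                            note = "tinnitus resolved; TLL set to 0")
    return(list(tll_db_sl = 0, trace = trace))
  }
  withr::with_seed(sub_seed(seed, "loudness"), {
    counts <- integer(0)
    steps <- vector("list", MAX_TRIALS)
    cur <- 0
    for (trial in seq_len(MAX_TRIALS)) {
      alt <- cur + 5
      pick_alt <- choose_alternative(listener$true_loudness_db_sl, cur, alt,
                                     listener$comparison_noise_db,
                                     listener$lapse_prob)
      choice <- if (pick_alt) alt else cur
      steps[[trial]] <- tibble::tibble(trial = trial, level1_db_sl = cur,
                                       level2_db_sl = alt, choice_db_sl = choice,
                                       note = sprintf("tone at %.0f Hz", pitch_hz))
      key <- as.character(choice)
      counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
      if (counts[[key]] >= 3L) {
        return(list(tll_db_sl = choice, trace = dplyr::bind_rows(steps[seq_len(trial)])))
      }
      cur <- choice
    }
  })
  stop("loudness match did not converge within ", MAX_TRIALS, " trials", call. = FALSE)
}

#' Minimum masking level by an ascending method
#'
#' Narrowband noise centred on the tinnitus pitch is raised from 0 dB in 5-dB
#' steps (5 s each); the minimum masking level (MML) is the first level at
#' which the tinnitus becomes inaudible. Internal noise perturbs the
#' audibility judgement. Resolved tinnitus returns 0 by convention.
#'
#' @param listener A `virtual_listener`.
#' @param seed Integer seed for response noise.
#' @param max_level_db Abandon the procedure above this level (default 120).
#' @return A list with `mml_db` and `trace`.
#' @export
minimum_masking_level <- function(listener, seed = 1L, max_level_db = 120) {
  stopifnot(inherits(listener, "virtual_listener"))
  if (!listener$tinnitus_present) {
    trace <- tibble::tibble(trial = 1L, level_db = NA_real_, masked = TRUE,
                            note = "tinnitus resolved; MML set to 0")
    return(list(mml_db = 0, trace = trace))
  }
  withr::with_seed(sub_seed(seed, "masking"), {
    levels <- seq(0, max_level_db, by = 5)
    steps <- vector("list", length(levels))
    for (i in seq_along(levels)) {
      lv <- levels[i]
      if (listener$lapse_prob > 0 && stats::runif(1) < listener$lapse_prob) {
        masked <- stats::runif(1) < 0.5
      } else {
        crit <- listener$true_masking_db +
          if (listener$comparison_noise_db > 0)
            stats::rnorm(1, 0, listener$comparison_noise_db) else 0
        masked <- lv >= crit
      }
      steps[[i]] <- tibble::tibble(trial = i, level_db = lv, masked = masked,
                                   note = "narrowband noise, 5 s")
      if (masked) {
        return(list(mml_db = lv, trace = dplyr::bind_rows(steps[seq_len(i)])))
      }
    }
  })
  stop("tinnitus not masked below ", max_level_db, " dB", call. = FALSE)
}

#' Residual inhibition test
#'
#' Presents narrowband noise centred on the tinnitus pitch at 10 dB SL above
#' the MML for 60 s, then asks whether the tinnitus percept decreased,
#' remained the same, or increased after stimulus offset. A decreased percept
#' classifies the listener as RI positive; unchanged or increased as RI
#' negative. With probability `lapse_prob` the reported percept is uniformly
#' random over the three alternatives.
#'
#' @param listener A `virtual_listener`.
#' @param mml_db The listener's measured MML in dB.
#' @param pitch_hz Centre frequency of the masking noise (metadata).
#' @param seed Integer seed for the lapse draw.
#' @return A list with `status` (`"positive"` or `"negative"`), `percept`
#'   (the reported percept) and `stimulus` (tibble: centre frequency, level =
#'   MML + 10 dB, duration 60 s).
#' @export
residual_inhibition_test <- function(listener, mml_db,
                                     pitch_hz = listener$true_pitch_hz, seed = 1L) {
  stopifnot(inherits(listener, "virtual_listener"))
  stimulus <- tibble::tibble(center_hz = pitch_hz, level_db = mml_db + 10,
                             duration_s = 60)
  percept <- withr::with_seed(sub_seed(seed, "ri"), {
    if (listener$lapse_prob > 0 && stats::runif(1) < listener$lapse_prob) {
      sample(c("decreased", "unchanged", "increased"), 1)
    } else if (listener$ri_positive) "decreased" else "unchanged"
  })
  status <- if (percept == "decreased") "positive" else "negative"
  list(status = status, percept = percept, stimulus = stimulus)
}

#' Score the Tinnitus Handicap Inventory
#'
#' 25 items answered yes / sometimes / no, scored 4 / 2 / 0 and summed, giving
#' an even total in `[0, 100]`.
#'
#' @param responses Character vector of exactly 25 responses among `"yes"`,
#'   `"sometimes"`, `"no"` (case-insensitive).
#' @return Integer THI total score.
#' @examples
#' score_thi(rep("yes", 25))   # 100
#' score_thi(c(rep("yes", 10), rep("sometimes", 5), rep("no", 10)))  # 50
#' @export
score_thi <- function(responses) {
  if (length(responses) != 25) {
    stop("the THI has exactly 25 items; got ", length(responses), call. = FALSE)
  }
  key <- c(yes = 4L, sometimes = 2L, no = 0L)
  r <- tolower(trimws(responses))
  if (!all(r %in% names(key))) {
    stop("responses must be 'yes', 'sometimes' or 'no'", call. = FALSE)
  }
  sum(key[r])
}

#' Run the full psychoacoustic assessment battery on a virtual listener
#'
#' Pitch match, loudness match (TLL), minimum masking level (MML) and the
#' residual inhibition test, chained as in the clinic: the pitch match feeds
#' the tone and noise centre frequencies, the MML sets the RI stimulus level.
#'
#' @param listener A `virtual_listener`.
#' @param seed Integer root seed; each procedure derives its own stream.
#' @return A list with `pitch_hz`, `tll_db_sl`, `mml_db`, `ri_status`, and
#'   `traces` (named list of procedure traces).
#' @export
assess_listener <- function(listener, seed = 1L) {
  stopifnot(inherits(listener, "virtual_listener"))
  if (!listener$tinnitus_present) {
    lm <- loudness_match(listener, seed = seed)
    mm <- minimum_masking_level(listener, seed = seed)
    return(list(pitch_hz = NA_real_, tll_db_sl = 0, mml_db = 0,
                ri_status = NA_character_,
                traces = list(loudness = lm$trace, masking = mm$trace)))
  }
  pm <- pitch_match(listener, seed = seed)
  lm <- loudness_match(listener, pitch_hz = pm$pitch_hz, seed = seed)
  mm <- minimum_masking_level(listener, seed = seed)
  ri <- residual_inhibition_test(listener, mm$mml_db, pitch_hz = pm$pitch_hz,
                                 seed = seed)
  list(pitch_hz = pm$pitch_hz, tll_db_sl = lm$tll_db_sl, mml_db = mm$mml_db,
       ri_status = ri$status,
       traces = list(pitch = pm$trace, loudness = lm$trace,
                     masking = mm$trace, ri = ri$stimulus))
}
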