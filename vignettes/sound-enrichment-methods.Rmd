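---
title: "Methods: individualized sound enrichment and study simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized sound enrichment and study simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnisim)
library(dplyr)
```

## What the package models

Sound enrichment is a tinnitus therapy that presents noise shaped to the
patient's hearing loss, with extra energy at the tinnitus pitch, on the
hypothesis that auditory input in the deprived frequency region reduces the
elevated spontaneous neural activity believed to underlie hearing-loss
related tinnitus. Whether a patient shows *residual inhibition* (RI) — a
temporary drop in tinnitus perception after a masking sound ends — plausibly
marks whether that spontaneous activity is drivable by sound at all, and so
may predict treatment response.

`tinnisim` implements the full measurement-to-analysis chain of a
two-group (RI+ vs RI−), four-timepoint (pre-treatment, 1, 3 and 6 months)
longitudinal evaluation of this therapy:

1. **Audiogram handling** — inclusion screening, hearing-loss band
   extraction, and the smoothing rule that adapts filter sharpness to the
   audiogram shape.
2. **Treatment-sound synthesis** — audiogram-shaped noise (v1), a
   tinnitus-pitch band component (v2), and their mono mix (v3), written as
   16-bit WAV.
3. **Psychoacoustic assessment** — pitch matching, tinnitus loudness level
   (TLL), minimum masking level (MML) and the RI test, run against a
   configurable virtual listener; THI questionnaire scoring.
4. **Cohort simulation** — a synthetic longitudinal cohort whose per-cell
   moments equal the published group tables, with compound-symmetry
   within-subject correlation.
5. **Statistics** — pooled-variance t-tests, a from-scratch two-way mixed
   (split-plot) ANOVA, the pooled one-way time ANOVA, Tukey HSD post hoc
   tests and the effect size r.

## Audiogram rules

Inclusion requires every threshold at or below 90 dB HL (strict "greater
than 90" exclusion), so the treatment sound can deliver audible input
across its whole spectrum.

The *hearing-loss band* spans the lowest to the highest test frequency whose
threshold exceeds a criterion. No published numeric criterion exists for
"hearing-loss frequency range", so the package adopts the standard clinical
cut of **25 dB HL**, configurable via `criterion_db`. Interior dips below
the criterion do not split the band; a single qualifying frequency is
widened to a half octave so the passband is usable.

The band-pass filter's edge sharpness follows a **smoothing parameter**
`s` in [1, 100]. The published description fixes four constraints: a 10-dB
adjacent-threshold difference maps to 80; differences of at least 20 dB are
"significant" and take *low* smoothing; values 1–10 count as low; flat
configurations take high smoothing. The piecewise-linear map

* `d < 20`: `s = 100 − 2d`
* `d ≥ 20`: `s = clamp(round(10 (40 − d)/20), 1, 10)`

honours all four, is monotone non-increasing, and places the jump exactly at
the 20-dB "significant" dichotomy. The discontinuity is intentional: it
mirrors the categorical rule rather than inventing a smooth interpolation
the source never describes.

## Synthesis chain and its numerical choices

White noise is Gaussian, zero mean, unit variance, at 44.1 kHz, reproducible
from a seed. Filtering is frequency-domain multiplication with raised-cosine
(Hann-shaped) skirts in log-frequency; the transition width is
`(s/100) × 1/3` octave per side, so `s = 100` gives a gentle 1/3-octave
skirt and `s = 1` a near-brick-wall 1/300 octave. Beyond one transition
width the gain is exactly zero, which makes the ≥ 40 dB stop-band assertion
trivially robust.

v1 applies a per-frequency gain of `threshold(f) − criterion` dB, linearly
interpolated in log-frequency between audiogram points: deeper loss gets
proportionally more energy, so the amplitude envelope follows the
hearing-loss configuration.

v2 is noise confined to 10% below and above the tinnitus pitch. Its in-band
amplitude profile is a raised-cosine bump peaked *at the pitch*, not a flat
passband. Two reasons: the design goal is a spectrum that peaks at the
tinnitus pitch, and a flat passband makes the spectral argmax a coin toss
among in-band bins (and, with a rising v1 underneath, lets bins just
outside the band win). A complex (non-tonal) tinnitus uses its pitch-match
frequency exactly as a tonal one does.

v3 = v1 + g·v2 in mono. The published description never states the mixing
ratio, so the package makes `boost_db` (default +6 dB) the *margin by which
the tinnitus band tops the rest of the spectrum*: `synthesize_treatment_sound()`
computes the analytic envelope maximum of v1 over the band and sets the
band-averaged v2 gain to that maximum plus `boost_db`. This guarantees the
global PSD peak falls inside (0.9·pitch, 1.1·pitch) for *any* admissible
audiogram, including steeply sloping ones where a fixed local boost would
be buried under the high-frequency envelope. `mix_v3()` alone keeps the
simpler semantics (boost relative to v1's own in-band level) for direct
use.

Output is peak-normalized to −1 dBFS, with a 50-ms crossfade of the tail
into the head so the 60-s default loops seamlessly. PSD estimates use
Welch averaging (4096-sample Hann segments, 50% overlap), scaled so the
one-sided density integrates to the waveform variance; all spectrum-report
numbers are therefore reproducible to Parseval consistency within 1%.

## The virtual listener

The simulated observer is a minimal standard psychophysics model: on each
two-alternative trial it picks the option closer to the ground truth after
adding Gaussian internal noise (`comparison_noise_db` on level scales;
`comparison_noise_db / 20` octaves on the pitch scale), and with
probability `lapse_prob` it responds at random. Ties go to the newly
proposed alternative so the adaptive track keeps moving.

**Pitch matching** starts from the 0.5/4 kHz pair; the next pair pits the
choice against the frequency one octave further in the chosen direction;
on a reversal (or at the grid boundary) the search refines in half-octave
steps around the candidate, alternating sides. Candidates live on a
half-octave grid anchored at 125 Hz whose last step below the 20 kHz test
ceiling is 16 kHz (the published procedure implies but never lists its
grid). Termination is three selections of the same frequency *during the
refinement stage*. Counting the coarse octave-stage choices as well would
let the octave candidate accrue two selections before any half-octave
neighbour is offered and then win a third against the first proposal — a
noiseless listener with a true pitch of 5 kHz would be returned 4 kHz
instead of the nearest grid point 5657 Hz. With stage-local counting, the
noiseless listener provably recovers the nearest grid frequency for every
true pitch, which the test suite checks exhaustively.

**TLL** ascends from threshold in the audiometer's 5-dB steps, terminating
on three selections of one level; 0 dB SL is valid. **MML** ascends from
0 dB in 5-dB steps until the tinnitus is judged inaudible; above 120 dB the
procedure aborts. **RI** presents pitch-centred narrowband noise at
MML + 10 dB for 60 s; a reported post-offset decrease classifies positive,
unchanged or increased classifies negative. On lapse trials the reported
percept is uniform over the three alternatives, so a positive listener with
lapse 0.1 is recovered with probability 1 − (2/3)(0.1) ≈ 0.93, which the
suite verifies against its binomial expectation. Resolved tinnitus returns
TLL = MML = 0 by the study convention. Contralateral 30 dB SL presentation
and ear routing are carried as trace metadata only.

## The synthetic cohort

Each subject × outcome draws a 4-vector from a multivariate normal whose
timepoint means and SDs equal the published per-cell tables (TLL, MML, THI
and four VAS scales, per group), with compound-symmetry correlation `rho`.
No covariance information was published; `rho = 0.5` is the default, a
middle value typical of repeated clinical measurements, and the acceptance
checks sweep 0.3/0.5/0.7. The conforming order is **draw → round to grid →
clamp**: TLL/MML to the nonnegative 5-dB grid, THI to even integers in
[0, 100], VAS clamped to [0, 10]. Eleven randomly chosen RI+ subjects are
"resolved" at month 6: their TLL and MML are set to 0 (THI and VAS stay as
drawn, matching the convention that only the psychoacoustic measures are
zeroed). Audiograms draw per-frequency independent normals from the group
threshold table, truncated to [−10, 90] dB HL and rounded to 5 dB.
Tinnitus pitch draws use the published group moments clipped to the stated
1–8 kHz range; those moments are mutually inconsistent as printed (a
7.2 ± 0.7 kHz normal essentially never reaches 1 kHz), and the package
follows the printed values rather than inventing corrected ones.

What the generator does *not* emulate: dropout (none was reported),
floor/ceiling response styles, learning effects across visits, or any
within-subject coupling between different outcomes. Passing tests therefore
demonstrate correctness of the pipeline under an idealized
moment-matched multivariate-normal cohort, not robustness to real
clinical data pathologies.

## Statistics

All tests are two-sided at α = .05. The two-way mixed ANOVA decomposes
the total sum of squares into group, subject-within-group, time,
group × time and within-subject residual strata; the group effect is tested
on (1, N−2) df against subject-within-group, the within-subject effects on
(3, 3(N−2)) df. Because every subject contributes one observation per
timepoint, group and time are orthogonal even with unequal group sizes, and
the decomposition agrees with `aov(y ~ group*time + Error(subject))` to
10 significant digits in the tests. No sphericity correction is applied
(none was used in the source analysis).

The *pooled* time ANOVA treats the four timepoints as independent groups —
df (3, 4n−4), i.e. (3, 148) for n = 38 and (3, 112) for n = 29 — which is
the degrees-of-freedom convention the published within-group statistics
print. It is statistically anticonservative in the mean-difference term and
conservative under the null with positive within-subject correlation; the
package provides it to reproduce the published convention and the proper
repeated-measures variant via `mixed_anova()` for users who want it.

Tukey HSD uses the studentized range statistic with adjusted p-values from
`stats::ptukey`, applied to the four timepoint levels within each group.
The effect size reported is `r = sqrt(F / (F + df2))`. Note the published
effect sizes follow no recoverable formula (e.g. F(1,65) = 15.45 published
with r = .51, whereas the formula gives 0.438); the package reports its own
r and does not attempt to match.

A known limitation found while validating against the published tables:
the RI− group's printed cell means decline enough, relative to their
printed SDs, that the pooled time ANOVA detects a within-RI− change for
TLL, MML and the severity VAS in almost every simulated replicate, whereas
the publication reports all within-RI− tests as non-significant (with
F/p pairs that are themselves mutually inconsistent). No generator faithful
to the printed moments can reproduce those non-significant results; the
package reports what the moments imply.

## Problem sizes and reproducibility

Simulation-based checks in the test suite use 200 replicate cohorts per
correlation value for the headline inference rates, 5000 replicates for the
type-I error calibration of the between-group test (SE ≈ 0.003 at α = .05),
100 randomized audiograms for the spectral-peak property, and 1000
repetitions for binomial response-model checks; synthesis tests use 1–2 s
waveforms, ample for Welch estimates with 4096-sample segments. Every
random stage derives a named substream from one root seed (cohort draws,
subject resolution, listener responses, v1/v2 noise), so identical seeds
give bit-identical cohorts, reports and WAV files, and individual stages
are reproducible in isolation.
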