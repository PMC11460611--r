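Package: tinnisim
Title: Individualized Tinnitus Sound-Enrichment Synthesis and Study Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for individualized tinnitus sound-enrichment therapy and for
    simulating the clinical study that evaluates it. Builds treatment sounds
    from a patient's audiogram (band-pass shaped noise spanning the hearing-loss
    range with extra energy at the tinnitus pitch), simulates the standard
    psychoacoustic assessment battery (two-alternative forced-choice pitch
    matching, tinnitus loudness level, minimum masking level, residual
    inhibition) against a configurable virtual listener, generates synthetic
    longitudinal cohorts with compound-symmetry correlation, and analyzes them
    with a from-scratch statistical battery: pooled-variance t-tests, two-way
    mixed (split-plot) ANOVA, pooled one-way time ANOVA, Tukey HSD post hoc
    tests and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
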