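Package: circaphase
Title: Single-Time-Point Circadian Phase Inference for Transcriptome
    Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Molecular-timetable analysis of circadian phase from
    single-time-point transcriptome snapshots under contrasting
    photoperiods. Provides a synthetic-data generator with known
    ground-truth rhythm parameters, harmonic-regression detection of
    cycling transcripts in diel time courses with the filter cascade
    and phase-binning conventions used for tomato, a fixed-period
    cosinor core, per-replicate internal-phase estimation from
    phase-annotated gene z-scores, two-way ANOVA with estimated
    marginal means for photoperiod-induced phase shifts, damped-cosine
    rhythm extraction from free-running leaf-movement traces, and a
    windowed heterozygous-variant scan for delineating introgressions
    in near-isogenic lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
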