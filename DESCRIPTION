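Package: fearphys
Title: Fiber Photometry and Slice Electrophysiology Analysis for Fear
    Conditioning Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and statistics toolkit for in vivo fiber
    photometry and ex vivo voltage-clamp recordings collected in cued
    fear-conditioning experiments. Implements the dual-channel (465 nm
    calcium-dependent / 405 nm isosbestic) peri-event delta-F/F pipeline
    with photobleaching detrending and motion-artifact subtraction;
    spontaneous EPSC event detection with amplitude and kinetic
    measurements; evoked-EPSC release-probability statistics
    (paired-pulse ratio, inverse squared coefficient of variation,
    variance-to-mean ratio, AMPA/NMDA ratio); assumption-gated group
    comparisons (Shapiro-Wilk, Levene, t-test / Mann-Whitney, one-way
    and mixed-design repeated-measures ANOVA); behavioral summary
    formulas; and seeded synthetic-data generators emulating
    photobleaching, shared motion artifacts, GCaMP6s tone-locked
    transients, Poisson-timed biexponential EPSCs and binomial quantal
    evoked release, so every pipeline stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    car,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
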