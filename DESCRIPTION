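Package: sandgait
Title: Human Walking Biomechanics on Deformable Sand Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing human walking on
    deformable substrates such as sand: coordinate-based gait event
    detection from marker trajectories, per-stride spatiotemporal
    parameters, foot sinkage depth estimation, whole-body centre-of-mass
    pendular energy-exchange statistics (recovery, relative amplitude,
    congruity), sagittal joint kinematics normalised to the gait cycle,
    surface EMG processing (high-pass filtering, rectification,
    participant normalisation, stride integration), and a statistical
    battery of one-dimensional statistical parametric mapping with
    random-field-theory and permutation thresholds, ANOVA with Tukey
    post hoc tests, Spearman correlograms ordered by the first principal
    component, and linear mixed-effect models. Includes a synthetic gait
    generator with complete ground truth so every stage has a
    parameter-recovery test, plus readers for C3D and tabular
    motion-capture trials.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
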