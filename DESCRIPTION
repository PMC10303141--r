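Package: platesensor
Title: Microplate-Reader Analysis of Biosensor Signals from Arrayed Microbial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genetically encoded fluorescent biosensor
    signals measured from arrayed microbial colonies with a monochromator
    microplate reader. Provides a long-format plate data model with layout
    annotation, ratiometric signal computation for dual-excitation sensors,
    oxidation-degree calculation for roGFP2-type redox probes normalized to
    fully reduced and fully oxidized controls, linear ratio-to-pH calibration
    with inverse prediction, Hill dose-response and fold-change screening
    statistics with one-way ANOVA and Tukey HSD group comparison, kinetic
    treatment-response classification with steady-state detection, grid-aware
    colony segmentation with size normalization, and a synthetic plate, trace
    and image generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
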