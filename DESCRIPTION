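Package: dichotr
Title: Directed Gamma-Band Connectivity for Dichotic Listening EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating interhemispheric auditory connectivity from
    region-of-interest (ROI) source time series. Implements lagged phase
    synchronization (a volume-conduction-robust functional connectivity
    measure) and isolated effective coherence (a directed, Granger-sense
    measure computed on a constrained multivariate autoregressive model),
    together with multi-trial MVAR fitting, a synthetic-data generator with
    known ground-truth directed coupling, and a group analysis pipeline
    (stimulus-locked windowing, gamma-band averaging, behavioral laterality
    index, Wilcoxon signed-rank and 2x2 repeated-measures ANOVA statistics
    with Holm correction). Results are returned as tibbles with tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
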