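Package: csdscope
Title: Cortical Spreading Depression and Epileptiform Activity Analysis for Awake-Mouse ECoG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of cortical spreading depression
    (CSD) and epileptiform activity in multi-channel DC-coupled
    electrocorticography (ECoG) from awake mice. Provides zero-phase
    signal conditioning, CSD event detection with propagation-speed
    estimation from paired electrodes, epileptiform spike and bout
    detection with onset, terminal-class and band-power severity scoring,
    normalized cross-correlation lag analysis between channels, and the
    nonparametric group-statistics battery used in CSD susceptibility
    studies (Mann-Whitney U, Kruskal-Wallis with Dunn-Bonferroni post hoc
    tests, slope t-tests and paired t-tests). A synthetic ECoG generator
    with known ground truth emulates KCl-evoked recordings in wild-type
    and FHM2 alpha2-Na+/K+-ATPase G301R mice so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
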