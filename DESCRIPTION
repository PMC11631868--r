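Package: phmrikit
Title: Dose-Response Pharmacological MRI, Connectivity, Lipidomics and
    Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for awake-rodent pharmacological MRI dose-response
    studies: voxel-wise BOLD percent-change maps with a ranked-p
    false-positive filter and atlas-based volume-of-activation tables
    (Kruskal-Wallis ranked, with rank-based effect sizes); resting-state
    region-to-region functional connectivity (band-pass, nuisance
    regression, Pearson/Fisher-Z matrices, group edge statistics, degree
    centrality, mutual-kNN clustering); rule-based differential lipidomics
    heatmaps (2-SD outlier rule, pooled t-tests, fold-change arrow and
    significance shade encodings, BDL/BAL states); and behavioral
    statistics (open-field ANOVA, novel-object investigation ratios,
    tail-flick latencies). Includes seeded synthetic-data generators for
    every input so each stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    RNifti,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
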