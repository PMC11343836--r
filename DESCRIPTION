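Package: sgscreen
Title: Spatial Gradient Screening for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised, cluster-free screening of expression gradients in
    spatial transcriptomic data. Infers how gene expression (or any numeric
    feature) changes as a function of distance to user-defined spatial
    reference features -- annotated tissue areas (polygons, optionally with
    holes) or linear trajectories -- using LOESS smoothing with a
    coverage-corrected span, tests each inferred gradient for non-randomness
    with a total-variation statistic against a permutation null, adjusts
    p-values by Benjamini-Hochberg, and classifies significant gradients by
    fit (MAE/RMSE) to predefined pattern models (descending, ascending,
    peaking). Includes a full simulation engine that generates Visium-like
    hexagonal lattices with patterned expression under controlled noise, a
    benchmarking grid, a reliability (R squared) estimator, and sensitivity
    experiments for perturbed reference features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    mgcv,
    Matrix,
    generics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
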