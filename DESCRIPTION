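Package: emergentdyn
Title: Causal Emergence, Ignition Hierarchy and Controllability of Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the capacity for causal emergence in multivariate
    (e.g. regional BOLD) timeseries via partial information decomposition and
    Integrated Information Decomposition, the spatiotemporal hierarchy of
    intrinsic-driven ignition, and the average and modal controllability of
    structural connectomes. Includes a dynamic mean-field whole-brain simulator
    with Balloon-Windkessel haemodynamics and functional-connectivity-dynamics
    fitting of the global coupling, a synthetic cohort generator with planted
    group effects for end-to-end validation, and group-level inference
    (ANOVA/ANCOVA, permutation t-tests with FDR control, rank correlations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
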