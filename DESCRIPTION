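Package: gripscan
Title: Event-Related Bimanual Grip-Force Simulation and Permutation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing event-related bimanual grip-force
    recordings from go/no-go attention experiments. Provides a fully
    synthetic generator of dual-channel force recordings with known ground
    truth (multiphasic evoked responses, lateralised hand-by-side effects,
    inter-hand coupling, drift and movement artifacts), signal
    preprocessing (zero-phase low-pass filtering, epoch extraction,
    baseline correction, threshold-based artifact rejection), an
    exploratory within-participant cluster-permutation scan of pointwise
    repeated-measures ANOVA statistics with threshold-free cluster
    enhancement (TFCE), and confirmatory window-averaged linear
    mixed-effects models including contralateral-force covariate models,
    marginal and conditional R-squared, per-participant random slopes and
    cross-experiment slope correlations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    yaml,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
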