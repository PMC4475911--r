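Package: spikefield
Title: Point-Process Encoding Models of Motor Cortex Spiking from LFP,
    Kinematics, and Spike History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Regularized point-process generalized linear models that quantify
    how much single-neuron spiking variability in motor cortex is explained by
    multiband local field potential (LFP) features, 3-D reach and grasp
    kinematics, and the neuron's own recent spiking history.  Provides a causal
    Butterworth filter bank with Hilbert analytic-signal phase and amplitude
    features and a causality audit, Savitzky-Golay velocity "pathlet" features,
    raised-cosine spike-history bases, L2-penalized conditional-intensity
    fitting, ROC-convex-hull predictive power under two-tier cross-validation
    with block-permutation chance levels, nested feature-set redundancy
    comparisons, and a synthetic-session generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    signal,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
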