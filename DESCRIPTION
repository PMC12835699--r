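Package: clgnet
Title: Conditional Linear Gaussian Bayesian Networks for Mixed Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-based structure learning and analysis of conditional linear
    Gaussian (CLG) Bayesian networks over mixed discrete/continuous clinical
    data, modelled on directed symptom-network studies of schizophrenia.
    Provides maximum-likelihood CLG parameter estimation with a decomposable
    BIC network score, greedy hill-climbing and tabu structure search under a
    continuous-to-discrete blacklist, bootstrap arc-strength model averaging,
    refitting of a learned graph as a recursive path model (standardized
    coefficients, Holm-adjusted p-values, CFI/TLI/RMSEA/AIC/BIC fit indices),
    node centrality statistics, Monte-Carlo conditional-probability queries on
    median-split events, iterative random-forest imputation of mixed data, and
    a synthetic generator that emulates the CATIE schizophrenia baseline
    roster with a known ground-truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
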