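Package: phiid
Title: Integrated Information Decomposition of Bipartite Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decomposes the time-delayed mutual information of a two-part
    stochastic process into sixteen information atoms over the product
    redundancy lattice, using either minimum-mutual-information (MMI) or
    common-change-in-surprisal (CCS) double-redundancy. Supports exact
    analysis of discrete systems given as joint probability mass functions,
    stationary Gaussian (vector-autoregressive) systems given analytically
    or estimated from multivariate time series, classical information-dynamics
    measures (active information storage, transfer entropy, whole-minus-sum
    and revised integrated information, causal density) as atom aggregates,
    a six-mode taxonomy of information dynamics, and pairwise decomposition
    of multivariate recordings with storage-transfer overlap analysis.
License: MIT
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
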