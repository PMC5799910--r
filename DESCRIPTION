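Package: assemblyscales
Title: Scale-Resolved Inference of Stochastic and Deterministic Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relative roles of deterministic (niche-based)
    and stochastic (neutral) processes in microbial community assembly across
    spatial scales. Implements null-model standardized phylogenetic turnover
    (MNTD, ses.MNTD/NTI, betaMNTD, betaNTI) with a fast taxa-shuffle null,
    distance-bin tables of per-scale process contributions, PCNM spatial
    eigenfunctions, rank-abundance model fitting (broken stick, preemption,
    lognormal, Zipf, Zipf-Mandelbrot) and the neutral zero-sum multinomial
    likelihood, redundancy-analysis variance partitioning with adjusted
    R-squared, distance decay and Mantel statistics, and a synthetic
    community generator with known assembly processes for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    phytools,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
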