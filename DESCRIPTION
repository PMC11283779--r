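Package: ouregimes
Title: Multi-Regime Ornstein-Uhlenbeck Models of Trait Evolution on
    Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Brownian motion, single-optimum and multi-optimum
    Ornstein-Uhlenbeck models of continuous trait evolution on dated
    phylogenies, univariate or multivariate on principal component
    scores, over stochastic character maps of discrete selective
    regimes.  Includes equal-rates Mk fitting and stochastic character
    map sampling, AICc model comparison, phylogenetic half-lives,
    parametric bootstrap confidence intervals for adaptive optima,
    Monte-Carlo power analysis against Brownian motion, log-shape-ratio
    size correction of linear morphometrics with fossil body-mass
    imputation, fossil grafting onto dated trees, and a synthetic-data
    generator so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
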