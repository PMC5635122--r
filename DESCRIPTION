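Package: prefdiff
Title: Preference-Influenced Learning and Diffusion Choice Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level computational models of preference learning under
    probabilistic feedback: an inter-trial Bayesian (or Rescorla-Wagner)
    belief process whose priors can be biased by one's own preferences and
    by item popularity, feeding an intra-trial drift diffusion choice
    process with a preference-biased starting point. Provides the Wiener
    first-passage-time likelihood over choices and response times,
    hierarchical Bayesian estimation of the competing model variants,
    predictive model comparison by Pareto-smoothed importance-sampling
    leave-one-out cross-validation (ELPD), agent-based simulations of the
    performance advantage conferred by egocentric influences, and synthetic
    data generators for schedule, preference-population and behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
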