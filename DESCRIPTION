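Package: obsaging
Title: Observer-Aging Effects in Long-Term Bird Survey Data
Version: 0.1.0
Authors@R: person("Robert", "Farnsworth", email = "rfarnsworth@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how observer aging degrades detection in
    long-term volunteer bird surveys. Provides seeded simulators for
    atlas-style detection/nondetection histories, Breeding Bird Survey
    (BBS)-style annual counts, and synthetic vocal waveforms; peak-frequency
    and spectral-heterogeneity classification of vocalizations; Bayesian
    hierarchical site-occupancy models with an observer-age detection
    contrast (adaptive Metropolis on the exactly marginalized likelihood);
    a BBS count pipeline (zero-filling, minimum observer age, exclusion
    filters, overdispersed Poisson generalized additive mixed models, pooled
    proportional-change curves); and weighted smooth regressions linking
    detection declines and published population trends to vocalization
    frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
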