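Package: rangedyn
Title: Dynamic Occupancy Modelling of Species Range Change Under
    Climate and Land-Use Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits persistence-colonization dynamic occupancy models on
    gridded presence-absence survey data, together with the logistic
    habitat-suitability surfaces and distance-weighted neighborhood
    occupancy (dispersal) covariates they condition on.  Candidate
    habitat formulae and dispersal kernels are enumerated and ranked by
    the Watanabe-Akaike information criterion; fitted models support
    decomposition of suitability change into climate and land-use
    fractions and stochastic forward projection of the occupied range
    under scenario bundles.  A synthetic-landscape generator provides
    spatially autocorrelated covariates and occupancy histories so the
    whole pipeline can be exercised and validated without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
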