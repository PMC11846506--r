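Package: gamvar
Title: Dynamic GAM-VAR State-Space Models for Multispecies Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Poisson state-space models for communities of interacting
    species observed as monthly capture counts. The latent log-mean of each
    species combines a hierarchical generalized additive model (shared and
    species-level distributed-lag smooths of minimum temperature, hierarchical
    linear effects of an NDVI moving average) with a first-order vector
    autoregression whose coefficient matrix is constrained to stationarity
    through a partial-autocorrelation reparameterization. Includes a
    No-U-Turn sampler with analytic gradients, Pareto-smoothed importance
    sampling leave-one-out model comparison, energy and variogram proper
    scoring rules, exact leave-future-out cross-validation, posterior
    predictive forecasting, generalized impulse-response analysis, covariate
    contrasts, and a synthetic community generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
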