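Package: resetMetaD
Title: Stochastic Resetting Combined with Well-Tempered Metadynamics on
    Model Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Langevin dynamics of a single particle on analytic
    two-dimensional model potentials, accelerated by well-tempered
    metadynamics along rotatable linear collective variables, by
    stochastic resetting (Poisson or sharp), or by both combined.
    Provides first-passage-time ensemble statistics (mean, coefficient
    of variation, empirical Laplace transform), a closed-form predictor
    of the mean first-passage time under Poisson resetting with
    optimal-rate search, and recovery of unbiased kinetics from biased
    trajectories via per-segment bias rescaling, product-limit survival
    estimation and exponential fitting. Includes a configuration-driven
    experiment runner and a synthetic first-passage ensemble generator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
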