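Package: topaug
Title: Topological Augmentation for Dynamic Models of Biochemical Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and localizes missing structure in ordinary
    differential equation (ODE) models of biochemical systems.  An ODE
    model is reformulated as a system of stochastic differential
    equations (SDEs) whose diffusion magnitudes quantify topological
    uncertainty; a continuous-discrete extended Kalman filter supplies a
    deterministic likelihood-based cost for any parameter point; the
    viable parameter space is explored with multi-chain
    Metropolis-Hastings sampling and ellipsoid-based characterization;
    diffusion-driven auxiliary states let the filter infer trajectories
    of hidden mechanisms; and candidate model extensions are ranked with
    Monte-Carlo Bayes factors.  Ships two executable case studies (a
    two-compartment pharmacokinetic model family and a yeast glutamine
    transport model family) with seeded synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
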