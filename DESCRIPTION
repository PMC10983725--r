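Package: denomcast
Title: Denominator Reconstruction for Refugee-Centre Health Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the "denominator problem" in refugee-centre health
    surveillance, where monthly walk-in-clinic patient counts and centre
    occupancy censuses are kept in fragmented records. Provides a synthetic
    centre-month panel generator with known ground truth, matching and
    exclusion rules for the two data streams, maximum-likelihood fitting of
    three regression relationships (a zero-inflated negative binomial model
    with a dispersion submodel and a latent first-order autoregressive
    process integrated out by Laplace approximation, and two Gaussian
    patient-occupancy ratio models with log-linear variance submodels),
    chained predictions of patients, occupancy and disease incidence with
    parametric-bootstrap uncertainty, and simulation-based residual
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    MASS,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
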