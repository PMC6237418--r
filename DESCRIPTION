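Package: comodyn
Title: Equation-Free Analysis of Collective Motion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting, classifying and predicting the latent
    dynamics of multi-agent collective motion without fitting explicit
    equations of motion. Includes a metric zonal (repulsion-orientation-
    attraction) schooling simulator producing swarm, torus and parallel
    regimes; projected dynamic mode decomposition (DMD) and DMD with
    reproducing kernels for observable time series; Koopman spectral kernels
    (principal-angle / Binet-Cauchy type) between fitted dynamical systems
    for classifying labeled trajectory segments; longitudinal and transverse
    dynamic structure factors with Brillouin-style dispersion fits; classical
    multidimensional scaling and Gaussian naive-Bayes cross-validated
    prediction; and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
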