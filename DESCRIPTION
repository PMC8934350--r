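Package: levyrisk
Title: Lifetime Cancer Risk from Levy Flights in Gene Expression Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional, parameter-free model of carcinogenesis in
    which tissue microstates perform random walks along the first principal
    axis of gene expression space. Implements the geometry stage (PC1
    direction, normal/tumor cloud centers and radii, fluctuation scale D
    from labelled expression matrices), closed-form lifetime-risk predictors
    for the Brownian (small-step diffusion with complementary-error-function
    escape) and Levy (rare Pareto-tailed jump) regimes, an extra-risk-score
    rescaling, ordinary-least-squares regression tests of both predictors
    against a packaged eight-tissue parameter table, a seedable discrete-time
    ensemble simulator with first-passage detection that validates the
    closed forms, and synthetic-data generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
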