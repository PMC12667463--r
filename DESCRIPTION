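Package: transmig
Title: Single-Cell Migration Analytics and Proliferation-Heterogeneity
    Simulation at Tumor-Tissue Matrix Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying whether tumor-tissue matrix
    interfaces instruct phenotype switching in migrating cancer cells or act
    as permissive filters. Provides mean-squared-displacement analysis of 3D
    single-cell tracks with snipping-based lag selection and diffusion
    coefficient estimation; a closed-form absorbing-boundary half-space
    diffusion model predicting interface transmigration (with a Monte-Carlo
    oracle and through-origin count regression); a stochastic simulator of
    the 96-well limiting-dilution proliferation-heterogeneity assay under
    systematic, stochastic, instructive and permissive subpopulation models
    with coefficient-of-variation profiles and nonparametric trend tests;
    and synthetic-data generators for Brownian, directed and two-compartment
    interface migration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
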