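Package: ahprsm
Title: Culture-Medium Optimization with the Analytic Hierarchy Process and
    Response Surface Methodology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria scoring of fermentation culture conditions and
    response-surface optimization of medium composition, as used in
    biosurfactant production studies. Single-factor screening experiments
    measuring biomass (OD600), protein concentration, surface tension and
    oil-displacement clear-zone diameter are converted into Saaty pairwise
    comparison matrices and ranked by the analytic hierarchy process (AHP),
    with geometric-mean prioritization and full consistency diagnostics
    (lambda_max, CI, RI, CR). Central composite designs are generated and
    fitted with a full second-order response-surface model, including a
    partial-SS ANOVA with lack-of-fit and pure-error decomposition, the R2
    family (ordinary, adjusted, PRESS-based predicted), stationary-point
    analysis and constrained optimum search. A synthetic-data module
    generates screen tables and design responses with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
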