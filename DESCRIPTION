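Package: glsmfa
Title: Generalized Least Squares Metabolic Flux Analysis with
    Simulation-Based Model Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frames overdetermined metabolic flux analysis (MFA) as a
    generalized least squares (GLS) regression: observed extracellular
    transport rates are whitened by the matrix square root of their
    propagated error covariance and intracellular fluxes are estimated by
    least squares, giving per-flux t-tests, confidence and prediction
    intervals, and the classical chi-square gross-measurement-error test.
    To separate model error from measurement uncertainty, stoichiometrically
    exact ("balanced") flux profiles are sampled uniformly from the model
    nullspace constrained by confidence bands on the observed fluxes
    (hit-and-run and mirror samplers), perturbed with measurement noise,
    and re-fit, yielding per-flux non-significance rates and error
    distributions against which a real-data fit can be judged.  Includes
    derivation of observed fluxes from metabolite-concentration and
    cell-density timecourses via regression splines with Monte-Carlo
    uncertainty propagation, a plain-text reaction-table format with a
    best-effort SBML subset reader, and generators for synthetic networks
    with known ground-truth fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    boot,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'flux-space.R'
    'gls.R'
    'glsmfa-package.R'
    'io.R'
    'model-ops.R'
    'noise.R'
    'reaction-table.R'
    'samplers.R'
    'sbml.R'
    'synthetic.R'
    'timecourse.R'
    'validation.R'
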