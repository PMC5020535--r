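#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## StoichiometricModel
## ---------------------------------------------------------------------------

#' Stoichiometric model
#'
#' A stoichiometric model of a metabolic network: a species-by-reaction matrix
#' of net stoichiometric coefficients (rows are balances on intracellular
#' species, columns are reactions, written products-positive) together with
#' per-reaction reversibility flags.  The steady-state mass balance is
#' `S %*% v = 0` for a flux vector `v` in nmol/1e6 cells/h.
#'
#' Objects are normally created by [parseReactionTable()], [readReactionTable()],
#' [readSBMLModel()] or [makeToyNetwork()], not by calling `new()` directly.
#'
#' @slot S numeric matrix of stoichiometric coefficients (species x reactions).
#' @slot species character vector of balanced species identifiers (row names).
#' @slot reactions character vector of reaction identifiers (column names).
#' @slot reversible logical vector, one flag per reaction.
#'
#' @seealso [partitionModel()], [nullspaceBasis()], [removeSpecies()],
#'   [addSpecies()]
#' @export
setClass("StoichiometricModel",
  representation(
    S = "matrix",
    species = "character",
    reactions = "character",
    reversible = "logical"
  )
)

setValidity("StoichiometricModel", function(object) {
  msg <- character()
  S <- object@S
  if (nrow(S) != length(object@species))
    msg <- c(msg, "nrow(S) must equal length(species)")
  if (ncol(S) != length(object@reactions))
    msg <- c(msg, "ncol(S) must equal length(reactions)")
  if (length(object@reversible) != length(object@reactions))
    msg <- c(msg, "one reversibility flag per reaction required")
  if (anyDuplicated(object@species))
    msg <- c(msg, "species names must be unique")
  if (anyDuplicated(object@reactions))
    msg <- c(msg, "reaction names must be unique")
  if (ncol(S) > 0 && nrow(S) > 0) {
    zero <- colSums(abs(S)) == 0
    if (any(zero))
      msg <- c(msg, paste0("reaction(s) with no balanced species: ",
                           paste(object@reactions[zero], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FluxPartition
## ---------------------------------------------------------------------------

#' Partition of a model into calculated and observed fluxes
#'
#' Splits the stoichiometry `S` column-wise into `S = [S_c | S_o]` where the
#' `S_o` columns correspond to observed (measured) transport fluxes and the
#' `S_c` columns to fluxes to be calculated by regression.  Index maps back
#' into the original column order are retained so that results can always be
#' reported in model order.
#'
#' @slot Sc numeric matrix, columns of calculated fluxes.
#' @slot So numeric matrix, columns of observed fluxes.
#' @slot calcNames,obsNames character, names in original model order.
#' @slot calcIdx,obsIdx integer, column indices into the original model.
#'
#' @seealso [partitionModel()], [fitGLS()]
#' @export
setClass("FluxPartition",
  representation(
    Sc = "matrix",
    So = "matrix",
    calcNames = "character",
    obsNames = "character",
    calcIdx = "integer",
    obsIdx = "integer"
  )
)

setValidity("FluxPartition", function(object) {
  msg <- character()
  if (nrow(object@Sc) != nrow(object@So))
    msg <- c(msg, "Sc and So must have identical rows (balances)")
  if (ncol(object@Sc) != length(object@calcNames))
    msg <- c(msg, "calcNames must match Sc columns")
  if (ncol(object@So) != length(object@obsNames))
    msg <- c(msg, "obsNames must match So columns")
  if (length(object@calcIdx) != ncol(object@Sc) ||
      length(object@obsIdx) != ncol(object@So))
    msg <- c(msg, "index maps must match block dimensions")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ObservedFluxes
## ---------------------------------------------------------------------------

#' Observed specific fluxes with uncertainties
#'
#' Measured extracellular transport rates (nmol/1e6 cells/h) and their
#' standard deviations.  Sign convention: consumption of an extracellular
#' species is positive, production negative (glucose uptake positive, lactate
#' secretion negative), matching the convention of transport reactions
#' written in the uptake direction.
#'
#' @slot values named numeric vector of fluxes.
#' @slot sd numeric vector of standard deviations, same length and order.
#'
#' @seealso [observedFluxes()], [readObservedFluxes()], [fluxTable()]
#' @export
setClass("ObservedFluxes",
  representation(values = "numeric", sd = "numeric")
)

setValidity("ObservedFluxes", function(object) {
  msg <- character()
  if (length(object@values) != length(object@sd))
    msg <- c(msg, "values and sd must have equal length")
  if (any(object@sd < 0))
    msg <- c(msg, "sd must be non-negative")
  if (is.null(names(object@values)))
    msg <- c(msg, "values must be named")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NoiseModel
## ---------------------------------------------------------------------------

#' Propagated balance-error covariance and whitening matrix
#'
#' The covariance of the balance residual `e = S_o %*% (v_o - E v_o)` is
#' `Cov(e) = S_o Cov(v_o) S_o^T`; balances that involve no observed flux give
#' zero rows, so a small jitter is added to every diagonal entry before
#' inversion (interpretable as residual uncertainty that each balance truly
#' closes).  With the residual scale sigma set to 1, `V = Cov(e)` and the
#' whitening matrix is the inverse of the unique symmetric positive-definite
#' square root `P` of `V` (`V = P %*% P`).
#'
#' @slot covEps covariance matrix of the balance error (flux units squared).
#' @slot V relative covariance matrix (equal to `covEps` with sigma = 1).
#' @slot Pinv inverse symmetric square root of `V`.
#' @slot jitter scalar (or per-balance vector) added to the diagonal.
#'
#' @seealso [estimateErrorCovariance()], [noiseModel()], [fitGLS()]
#' @export
setClass("NoiseModel",
  representation(
    covEps = "matrix",
    V = "matrix",
    Pinv = "matrix",
    jitter = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (nrow(object@V) != ncol(object@V))
    msg <- c(msg, "V must be square")
  if (!isTRUE(all.equal(object@V, t(object@V), tolerance = 1e-8)))
    msg <- c(msg, "V must be symmetric")
  W <- object@Pinv %*% object@V %*% t(object@Pinv)
  if (max(abs(W - diag(nrow(W)))) > 1e-6)
    msg <- c(msg, "Pinv must whiten V (Pinv V Pinv^T = I)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GLSFit
## ---------------------------------------------------------------------------

#' Generalized least squares flux fit
#'
#' Result of regressing the whitened observed balance load `-P^-1 S_o v_o`
#' on the whitened calculated-flux stoichiometry `P^-1 S_c`.  Contains the
#' estimated fluxes, whitened residuals, the residual variance estimate
#' sigma2Hat (approximately 1 when both model and error covariance are
#' correct), standard errors and t-statistics.
#'
#' The degrees of freedom follow `dfConvention`: `"textbook"` uses
#' `n_b - n_c - 1` (the intercept-style formula commonly printed for
#' regression); `"residual"` uses the exact residual degrees of freedom
#' `n_b - n_c` of this no-intercept regression, under which sigma2Hat is
#' unbiased for 1.
#'
#' @slot vHat named numeric, estimated calculated fluxes (nmol/1e6 cells/h).
#' @slot se,tStat,p numeric, per-flux standard errors, t-statistics and
#'   two-sided p-values.
#' @slot residW numeric, whitened residuals (one per balance).
#' @slot sigma2Hat numeric scalar, residual variance estimate.
#' @slot df numeric scalar, degrees of freedom used for sigma2Hat and t.
#' @slot covVhat covariance matrix of the estimates.
#' @slot nb,nc integer, number of balances and of calculated fluxes.
#' @slot Xw,yw whitened design matrix and response (kept for prediction
#'   intervals and diagnostics).
#' @slot dfConvention character, `"textbook"` or `"residual"`.
#'
#' @seealso [fitGLS()], [tTest()], [confidenceIntervals()],
#'   [chi2GrossErrorTest()]
#' @export
setClass("GLSFit",
  representation(
    vHat = "numeric",
    se = "numeric",
    tStat = "numeric",
    p = "numeric",
    residW = "numeric",
    sigma2Hat = "numeric",
    df = "numeric",
    covVhat = "matrix",
    nb = "integer",
    nc = "integer",
    Xw = "matrix",
    yw = "numeric",
    dfConvention = "character"
  )
)

setValidity("GLSFit", function(object) {
  msg <- character()
  n <- length(object@vHat)
  if (length(object@se) != n || length(object@tStat) != n || length(object@p) != n)
    msg <- c(msg, "vHat, se, tStat and p must be aligned")
  if (any(object@se < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FluxSpace
## ---------------------------------------------------------------------------

#' Feasible balanced-flux polytope in nullspace coordinates
#'
#' Any flux vector satisfying `S v = 0` can be written `v = K b` for the
#' orthonormal nullspace basis `K`; bounding each observed flux `v_i = K_i b`
#' by a confidence band `v_i +/- a * sd(v_i)` yields a linear inequality
#' system `A b <= u` on the basis coordinates.  Unbounded basis directions are
#' additionally boxed so that the polytope is bounded.
#'
#' @slot K nullspace basis (reactions x basis dimension), orthonormal columns.
#' @slot A,u inequality system `A %*% b <= u`.
#' @slot obsRows integer indices (into reactions) of the constrained fluxes.
#' @slot a numeric, the confidence-band multiplier used for the bounds.
#' @slot reactionNames character, names for the rows of `K`.
#'
#' @seealso [buildConstraints()], [findInteriorPoint()], [sampleHitAndRun()],
#'   [sampleMirror()]
#' @export
setClass("FluxSpace",
  representation(
    K = "matrix",
    A = "matrix",
    u = "numeric",
    obsRows = "integer",
    a = "numeric",
    reactionNames = "character"
  )
)

setValidity("FluxSpace", function(object) {
  msg <- character()
  if (ncol(object@A) != ncol(object@K))
    msg <- c(msg, "A must act on basis coordinates (ncol(A) == ncol(K))")
  if (nrow(object@A) != length(object@u))
    msg <- c(msg, "u must have one entry per inequality row")
  if (length(object@reactionNames) != nrow(object@K))
    msg <- c(msg, "reactionNames must match rows of K")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## BalancedFluxSample
## ---------------------------------------------------------------------------

#' Sample of balanced flux profiles
#'
#' Basis points drawn from a [FluxSpace] and the corresponding flux profiles
#' `v = K b` (rows are samples).  Every sampled profile satisfies `S v = 0`
#' to machine precision by construction.
#'
#' @slot basisPoints numeric matrix, samples x basis dimension.
#' @slot fluxes numeric matrix, samples x reactions.
#' @slot algorithm character tag (`"hit-and-run"` or `"mirror"`).
#' @slot diagnostics list of chain diagnostics (degenerate-chord or rejected
#'   step counts, effective sample sizes, step size).
#' @slot seed integer seed the chain was run with.
#' @export
setClass("BalancedFluxSample",
  representation(
    basisPoints = "matrix",
    fluxes = "matrix",
    algorithm = "character",
    diagnostics = "list",
    seed = "integer"
  )
)

## ---------------------------------------------------------------------------
## SimulationDesign / SimulationResult
## ---------------------------------------------------------------------------

#' Design of a balanced-flux validation simulation
#'
#' @slot nProfiles integer, number of balanced profiles to sample.
#' @slot mNoise integer, number of noise replicates per profile.
#' @slot noiseSource `"sd"` (use the observed per-flux standard deviations)
#'   or `"cv"` (uniform coefficient of variation applied to each profile's
#'   true observed fluxes).
#' @slot cv numeric fraction (e.g. 0.05 for 5 %), used when
#'   `noiseSource == "cv"`.
#' @slot alpha significance level for the t- and chi-square tests.
#' @slot seed integer seed.
#' @slot dfConvention df convention passed to the GLS fit.
#' @seealso [simulationDesign()], [runValidation()]
#' @export
setClass("SimulationDesign",
  representation(
    nProfiles = "integer",
    mNoise = "integer",
    noiseSource = "character",
    cv = "numeric",
    alpha = "numeric",
    seed = "integer",
    dfConvention = "character"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@nProfiles < 1L || object@mNoise < 1L)
    msg <- c(msg, "nProfiles and mNoise must be >= 1")
  if (object@noiseSource == "cv" && (length(object@cv) != 1 || object@cv < 0))
    msg <- c(msg, "cv must be a single non-negative fraction")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Aggregated results of a balanced-flux validation simulation
#'
#' Pooled over all `nProfiles x mNoise` replicates: per-calculated-flux
#' non-significance percentages, the chi-square rejection rate, per-replicate
#' percent errors against the known true fluxes, and per-replicate residual
#' variance estimates.
#'
#' @slot nonsigPct named numeric, percent of replicates in which each
#'   calculated flux was non-significant.
#' @slot chi2RejectPct numeric scalar, percent of replicates rejected by the
#'   gross-measurement-error chi-square test.
#' @slot errPct numeric matrix (replicates x calculated fluxes), percent
#'   error `100 |vhat - v_true| / |v_true|`; `NA` where `|v_true|` is below
#'   `zeroTol`.
#' @slot sigMatrix logical matrix (replicates x calculated fluxes).
#' @slot sigma2 numeric vector of per-replicate sigma2Hat values.
#' @slot trueCalc numeric matrix (profiles x calculated fluxes) of the true
#'   calculated fluxes of each sampled profile.
#' @slot ciHalfWidth named numeric, median CI half-width per flux.
#' @slot profileIndex integer vector mapping replicates to profiles.
#' @slot calcNames character.
#' @slot design the [SimulationDesign] used.
#' @seealso [runValidation()], [rankSummaries()], [compareToObserved()]
#' @export
setClass("SimulationResult",
  representation(
    nonsigPct = "numeric",
    chi2RejectPct = "numeric",
    errPct = "matrix",
    sigMatrix = "matrix",
    sigma2 = "numeric",
    trueCalc = "matrix",
    ciHalfWidth = "numeric",
    profileIndex = "integer",
    calcNames = "character",
    design = "SimulationDesign"
  )
)

setValidity("SimulationResult", function(object) {
  msg <- character()
  if (any(object@nonsigPct < -1e-9 | object@nonsigPct > 100 + 1e-9))
    msg <- c(msg, "nonsigPct must lie in [0, 100]")
  if (ncol(object@errPct) != length(object@calcNames))
    msg <- c(msg, "errPct must have one column per calculated flux")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SmoothFit
## ---------------------------------------------------------------------------

#' Regression-spline fit to a timecourse
#'
#' A cubic B-spline basis expansion of fixed dimension (default 4 basis
#' functions, i.e. the cubic polynomial space) fit by least squares to a
#' metabolite-concentration or cell-density timecourse.  The derivative is
#' the exact analytic derivative of the basis expansion.
#'
#' @slot knots full B-spline knot vector (order 4).
#' @slot coef basis coefficients.
#' @slot residualVar residual mean square of the observations about the fit.
#' @slot t,y the data the fit was computed from.
#' @slot nBasis basis dimension.
#' @seealso [fitTimecourse()], [predictSmooth()], [simulateFluxDistribution()]
#' @export
setClass("SmoothFit",
  representation(
    knots = "numeric",
    coef = "numeric",
    residualVar = "numeric",
    t = "numeric",
    y = "numeric",
    nBasis = "integer"
  )
)

## ---------------------------------------------------------------------------
## ToyScenario
## ---------------------------------------------------------------------------

#' Synthetic network scenario with known ground truth
#'
#' A small stoichiometric network together with a full flux vector satisfying
#' `S v = 0` to machine precision, the subset of reactions treated as
#' observed, and the noise specification for the observed fluxes.
#'
#' @slot model a [StoichiometricModel].
#' @slot trueFluxes named numeric, full flux vector (model reaction order).
#' @slot observed character, names of the observed reactions.
#' @slot obs an [ObservedFluxes] built from the true observed fluxes and the
#'   noise specification.
#' @slot cv numeric fraction used to set the observation sd.
#' @slot seed integer.
#' @seealso [makeToyNetwork()], [makeMisfitScenario()], [makeTimecourse()]
#' @export
setClass("ToyScenario",
  representation(
    model = "StoichiometricModel",
    trueFluxes = "numeric",
    observed = "character",
    obs = "ObservedFluxes",
    cv = "numeric",
    seed = "integer"
  )
)

setValidity("ToyScenario", function(object) {
  msg <- character()
  res <- max(abs(object@model@S %*% object@trueFluxes))
  if (res > 1e-10)
    msg <- c(msg, sprintf("trueFluxes must satisfy S v = 0 (residual %.2e)", res))
  if (!all(object@observed %in% object@model@reactions))
    msg <- c(msg, "observed reactions must exist in the model")
  if (length(msg)) msg else TRUE
})
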