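#' @include AllClasses.R
NULL

.spline.knots <- function(t, nBasis) {
  bk <- range(t)
  nInterior <- nBasis - 4L
  interior <- if (nInterior > 0)
    stats::quantile(t, probs = seq_len(nInterior) / (nInterior + 1),
                    names = FALSE)
  else numeric()
  c(rep(bk[1], 4), interior, rep(bk[2], 4))
}

.spline.design <- function(knots, t, deriv = 0L) {
  splines::splineDesign(knots, t, ord = 4L, derivs = rep(deriv, length(t)))
}

#' Fit a regression spline to a timecourse
#'
#' Fits a cubic B-spline basis of dimension `nBasis` (default 4, i.e. the
#' cubic polynomial space; larger bases place interior knots at quantiles of
#' `t`) to a metabolite-concentration or cell-density timecourse by
#' unpenalized least squares.  The measurement variance is estimated as the
#' residual mean square of the observations about the fit.
#'
#' @param t sampling times (h), strictly increasing.
#' @param y measured values (concentration, or cells/mL for density).
#' @param nBasis number of cubic basis functions (>= 4).
#' @return A [SmoothFit]; evaluate it with [predictSmooth()].
#' @export
fitTimecourse <- function(t, y, nBasis = 4) {
  nBasis <- as.integer(nBasis)
  if (nBasis < 4L)
    stop("at least 4 cubic basis functions are required", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if (length(t) != length(y))
    stop("t and y must be the same length", call. = FALSE)
  if (length(t) <= nBasis)
    stop("need more than ", nBasis, " points to fit ", nBasis,
         " basis functions", call. = FALSE)
  knots <- .spline.knots(t, nBasis)
  B <- .spline.design(knots, t)
  fit <- stats::lm.fit(B, y)
  rdf <- length(y) - nBasis
  methods::new("SmoothFit", knots = knots, coef = unname(fit$coefficients),
               residualVar = sum(fit$residuals^2) / rdf,
               t = as.numeric(t), y = as.numeric(y), nBasis = nBasis)
}

#' Evaluate a spline fit or its derivative
#'
#' The derivative is the exact analytic derivative of the fitted basis
#' expansion (not a finite difference).
#'
#' @param fit a [SmoothFit].
#' @param t evaluation times, within the fitted range.
#' @param deriv 0 for the curve, 1 for its first derivative.
#' @return numeric vector.
#' @export
predictSmooth <- function(fit, t, deriv = 0L) {
  rng <- range(fit@t)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
    stop("evaluation time outside the fitted range [", rng[1], ", ", rng[2],
         "]", call. = FALSE)
  t <- pmin(pmax(t, rng[1]), rng[2])
  drop(.spline.design(fit@knots, t, deriv = as.integer(deriv)) %*% fit@coef)
}

#' Monte-Carlo distribution of a specific flux at one time point
#'
#' Propagates timecourse uncertainty into the flux: for each replicate the
#' fitted concentration curve's predictions at the original sampling times
#' are perturbed with normal noise whose variance is the sum of the
#' regression variance (prediction variance of the curve) and the
#' measurement variance, the spline is re-fit, and the specific flux
#' `v = -(1/X) dC/dt` (uptake convention: consumption positive) is evaluated
#' at `tStar`.  The cell-density fit is perturbed and re-fit the same way,
#' pairing the k-th concentration replicate with the k-th density replicate.
#'
#' @param fitC [SmoothFit] of the metabolite concentration.
#' @param fitX [SmoothFit] of the cell density.
#' @param tStar evaluation time (h), within both fitted ranges.
#' @param n number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @param measurementVar measurement variance added to the regression
#'   variance; defaults to the fit's residual variance.
#' @param convention `"uptake"` (consumption positive, the reporting
#'   convention of the observed-flux tables) or `"derivative"`
#'   (`v = +(1/X) dC/dt`).
#' @param perturbX whether to propagate density uncertainty too.
#' @return list with `mean`, `var`, `sd`, `cv` (percent) and the replicate
#'   `samples`.
#' @export
simulateFluxDistribution <- function(fitC, fitX, tStar, n = 1000, seed = 1,
                                     measurementVar = NULL,
                                     convention = c("uptake", "derivative"),
                                     perturbX = TRUE) {
  convention <- match.arg(convention)
  set.seed(seed)
  mVar <- if (is.null(measurementVar)) fitC@residualVar else measurementVar
  dCdt <- .resample.deriv(fitC, tStar, n, mVar)
  X <- if (perturbX) .resample.value(fitX, tStar, n, fitX@residualVar)
       else rep(predictSmooth(fitX, tStar), n)
  v <- dCdt / X
  if (convention == "uptake") v <- -v
  list(mean = mean(v), var = stats::var(v), sd = stats::sd(v),
       cv = 100 * stats::sd(v) / abs(mean(v)), samples = v)
}

## perturb fitted values at the original times and refit; return derivative
## (or value) replicates at tStar
.resample.core <- function(fit, tStar, n, measurementVar, deriv) {
  B <- .spline.design(fit@knots, fit@t)
  qrB <- qr(B)
  fitted <- drop(B %*% fit@coef)
  ## regression variance of the curve at the sampled points (leverage based)
  XtXinv <- chol2inv(chol(crossprod(B)))
  lev <- rowSums((B %*% XtXinv) * B)
  sdPts <- sqrt(fit@residualVar * lev + measurementVar)
  Y <- fitted + matrix(stats::rnorm(length(fitted) * n, sd = rep(sdPts, n)),
                       ncol = n)
  coefs <- qr.coef(qrB, Y)
  drop(.spline.design(fit@knots, tStar, deriv = deriv) %*% coefs)
}

.resample.deriv <- function(fit, tStar, n, measurementVar)
  .resample.core(fit, tStar, n, measurementVar, 1L)

.resample.value <- function(fit, tStar, n, measurementVar)
  .resample.core(fit, tStar, n, measurementVar, 0L)

#' Derive an observed-flux table from timecourse fits
#'
#' Applies [simulateFluxDistribution()] to each metabolite fit at `tStar`
#' and assembles an [ObservedFluxes] from the Monte-Carlo means and standard
#' deviations.  Biomass pseudo-fluxes (protein, lipids, DNA, RNA,
#' carbohydrates, ...) are appended from a composition table: each component
#' flux is `-coef * mu * dryMass`, where `coef` is the component content in
#' nmol per mg dry cells, `mu = X'(tStar)/X(tStar)` is the specific growth
#' rate (1/h) and `dryMass` the dry cell mass (mg/1e6 cells, default 0.24);
#' the sign is negative because biomass components are produced.
#' Their uncertainty is propagated from the density fit's Monte-Carlo
#' growth-rate replicates.
#'
#' @param fitsC named list of metabolite [SmoothFit]s.
#' @param fitX [SmoothFit] of cell density.
#' @param tStar evaluation time (h).
#' @param n Monte-Carlo replicates per metabolite.
#' @param seed integer seed (per-metabolite substreams are derived from it).
#' @param composition optional named numeric vector, component content in
#'   nmol/mg dry cells.
#' @param dryMass dry cell mass, mg/1e6 cells.
#' @param convention sign convention, see [simulateFluxDistribution()].
#' @return An [ObservedFluxes].
#' @export
fluxTable <- function(fitsC, fitX, tStar, n = 1000, seed = 1,
                      composition = NULL, dryMass = 0.24,
                      convention = c("uptake", "derivative")) {
  convention <- match.arg(convention)
  if (!methods::is(fitX, "SmoothFit"))
    stop("a cell-density fit is required", call. = FALSE)
  nms <- names(fitsC)
  vals <- sds <- numeric(length(fitsC))
  for (k in seq_along(fitsC)) {
    dist <- simulateFluxDistribution(fitsC[[k]], fitX, tStar, n = n,
                                     seed = seed + k,
                                     convention = convention)
    vals[k] <- dist$mean
    sds[k] <- dist$sd
  }
  names(vals) <- nms
  if (!is.null(composition)) {
    set.seed(seed)
    Xv <- .resample.value(fitX, tStar, n, fitX@residualVar)
    set.seed(seed)
    Xd <- .resample.deriv(fitX, tStar, n, fitX@residualVar)
    mu <- Xd / Xv
    bio <- -outer(mu, composition * dryMass)   # n x components, produced
    vals <- c(vals, colMeans(bio))
    sds <- c(sds, apply(bio, 2, stats::sd))
  }
  methods::new("ObservedFluxes", values = vals, sd = sds)
}
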