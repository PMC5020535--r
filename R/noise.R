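#' @include AllClasses.R
NULL

## symmetric positive-definite inverse square root
.sym.inv.sqrt <- function(V, tol = 1e-12) {
  e <- eigen(V, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values)))
    stop("covariance matrix is singular (or nearly so) even after jitter; ",
         "increase the jitter", call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Construct a noise model from an explicit relative covariance
#'
#' Direct constructor for [NoiseModel], useful when `V` is known (e.g.
#' `V = I` for ordinary least squares, or in tests).  The whitening matrix is
#' the inverse of the unique symmetric square root of `V`
#' (eigendecomposition); a Cholesky-based whitener gives an equivalent fit
#' and is available via `sqrtMethod = "chol"`.
#'
#' @param V symmetric positive-definite relative covariance matrix.
#' @param jitter value already included in `V`'s diagonal (bookkeeping only).
#' @param sqrtMethod `"symmetric"` (default) or `"chol"`.
#' @return A [NoiseModel].
#' @export
noiseModel <- function(V, jitter = 0, sqrtMethod = c("symmetric", "chol")) {
  sqrtMethod <- match.arg(sqrtMethod)
  V <- (V + t(V)) / 2
  Pinv <- if (sqrtMethod == "symmetric") {
    .sym.inv.sqrt(V)
  } else {
    ## V = L L^T; P^-1 = L^-1 whitens just as well (whitening is unique up
    ## to rotation, and the GLS fit is rotation-invariant)
    R <- tryCatch(chol(V), error = function(e)
      stop("covariance matrix is not positive definite", call. = FALSE))
    backsolve(R, diag(nrow(V)), transpose = TRUE)
  }
  methods::new("NoiseModel", covEps = V, V = V, Pinv = Pinv,
               jitter = as.numeric(jitter))
}

#' Propagate observed-flux uncertainty to the balance errors
#'
#' Computes `Cov(e) = S_o %*% Cov(v_o) %*% t(S_o)` and adds a jitter to every
#' diagonal entry.  Balances around species with no observed flux have zero
#' rows in the propagated covariance; the jitter encodes the (small)
#' uncertainty that those balances truly close, and makes the matrix
#' invertible.  With the residual scale sigma set to 1, `V = Cov(e)` and only
#' relative variances matter: the overall scale is absorbed by the residual
#' variance estimate of the fit.
#'
#' @param partition a [FluxPartition].
#' @param obs an [ObservedFluxes]; its `sd` builds the default diagonal
#'   `Cov(v_o)`.
#' @param obsCov optional full covariance of the observed fluxes (overrides
#'   the diagonal default).
#' @param jitter scalar or per-balance vector added to the diagonal.  The
#'   default is `1e-6 * median(nonzero diagonal of S_o Cov(v_o) S_o^T)`,
#'   which is scale-free; supply a vector to encode more uncertainty around
#'   specific balances.
#' @param sqrtMethod passed to [noiseModel()].
#' @return A [NoiseModel].
#' @export
estimateErrorCovariance <- function(partition, obs, obsCov = NULL,
                                    jitter = NULL,
                                    sqrtMethod = c("symmetric", "chol")) {
  sqrtMethod <- match.arg(sqrtMethod)
  So <- partition@So
  if (length(obs@values) != ncol(So))
    stop("observed fluxes do not match the partition (", ncol(So),
         " observed columns)", call. = FALSE)
  if (is.null(obsCov)) {
    obsCov <- diag(obs@sd^2, nrow = length(obs@sd))
  } else {
    obsCov <- (obsCov + t(obsCov)) / 2
    ev <- eigen(obsCov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("obsCov is not positive semi-definite", call. = FALSE)
  }
  cov0 <- So %*% obsCov %*% t(So)
  dg <- diag(cov0)
  if (is.null(jitter)) {
    nz <- dg[dg > 0]
    jitter <- if (length(nz)) 1e-6 * stats::median(nz) else 1e-6
  }
  if (!length(jitter) %in% c(1L, nrow(cov0)))
    stop("jitter must be a scalar or one value per balance", call. = FALSE)
  V <- cov0 + diag(rep_len(jitter, nrow(cov0)), nrow(cov0))
  nm <- noiseModel(V, jitter = jitter, sqrtMethod = sqrtMethod)
  nm
}
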