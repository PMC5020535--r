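#' @include AllClasses.R
NULL

#' Build the constrained balanced-flux space
#'
#' Encodes confidence bands on the observed fluxes as linear inequalities on
#' the nullspace basis coordinates: for each observed reaction `i` (a row
#' `K_i` of the basis), `v_i - a*sd_i <= K_i b <= v_i + a*sd_i`.  The band
#' multiplier `a` defaults to the two-sided 99 % normal quantile (2.576),
#' wide enough to include practically all plausible flux values; pass
#' `a = qt(0.995, df)` for a t-based band.  Alternatively, explicit
#' `lower`/`upper` bounds per observed flux may be given (e.g. min/max of
#' confidence bands over a time window).
#'
#' Because the band constraints alone can leave basis directions unbounded,
#' every basis coordinate is additionally boxed at
#' `+/- boxFactor * max(|bound|)`; this is reported with a message.
#'
#' @param K orthonormal nullspace basis ([nullspaceBasis()]).
#' @param obsRows integer indices of the observed reactions (rows of `K`).
#' @param obs an [ObservedFluxes] giving centers and sds, or `NULL` when
#'   `lower`/`upper` are supplied.
#' @param a band multiplier.
#' @param lower,upper optional explicit bounds (same length as `obsRows`).
#' @param boxFactor box half-width multiplier for the basis coordinates.
#' @param tol bands narrower than `2*tol` (e.g. `sd = 0`) are widened to
#'   `+/- tol` with a warning.
#' @param reactionNames optional names for the rows of `K`.
#' @return A [FluxSpace].
#' @export
buildConstraints <- function(K, obsRows, obs = NULL, a = stats::qnorm(0.995),
                             lower = NULL, upper = NULL, boxFactor = 10,
                             tol = 1e-9, reactionNames = NULL) {
  d <- ncol(K)
  obsRows <- as.integer(obsRows)
  if (is.null(lower) || is.null(upper)) {
    stopifnot(!is.null(obs))
    if (length(obs@values) != length(obsRows))
      stop("obs must align with obsRows", call. = FALSE)
    lower <- obs@values - a * obs@sd
    upper <- obs@values + a * obs@sd
  }
  if (any(lower > upper))
    stop("infeasible bounds: lower > upper for flux(es) ",
         paste(which(lower > upper), collapse = ", "), call. = FALSE)
  narrow <- (upper - lower) < 2 * tol
  if (any(narrow)) {
    warning(sum(narrow), " flux bound(s) collapse to equality; widened to a ",
            "+/-", format(tol), " band")
    mid <- (upper + lower) / 2
    lower[narrow] <- mid[narrow] - tol
    upper[narrow] <- mid[narrow] + tol
  }
  Kobs <- K[obsRows, , drop = FALSE]
  A <- rbind(Kobs, -Kobs)
  u <- unname(c(upper, -lower))
  B <- boxFactor * max(abs(c(lower, upper)), 1e-6)
  message("boxing basis coordinates at +/- ", format(B, digits = 4),
          " to keep the flux polytope bounded")
  A <- rbind(A, diag(d), -diag(d))
  u <- c(u, rep(B, 2 * d))
  if (is.null(reactionNames))
    reactionNames <- paste0("r", seq_len(nrow(K)))
  methods::new("FluxSpace", K = K, A = A, u = u, obsRows = obsRows,
               a = as.numeric(a), reactionNames = as.character(reactionNames))
}

#' Convenience wrapper: flux space straight from a model
#'
#' Computes the nullspace of the model and builds the constrained space for
#' the given observed reactions.
#'
#' @param model a [StoichiometricModel].
#' @param observed character vector of observed reaction names.
#' @param obs an [ObservedFluxes] aligned to `observed`.
#' @param ... passed to [buildConstraints()].
#' @return A [FluxSpace].
#' @export
fluxSpace <- function(model, observed, obs, ...) {
  K <- nullspaceBasis(model@S)
  if (ncol(K) == 0L)
    stop("model has a trivial nullspace: no balanced flux profiles exist",
         call. = FALSE)
  buildConstraints(K, obsRows = match(observed, model@reactions), obs = obs,
                   reactionNames = model@reactions, ...)
}

## Chebyshev-center LP via boot::simplex.  The system is rescaled for the
## solver: rows are normalized, variables shifted to >= 0 using the box
## bound that buildConstraints always installs, and expressed in box units.
.chebyshev.lp <- function(A, u, B) {
  d <- ncol(A)
  nrm <- sqrt(rowSums(A^2))
  ## all-zero constraint rows: vacuous if u >= 0, otherwise a certificate
  ## of emptiness (0 <= u_i < 0 is impossible)
  tiny <- nrm <= 1e-12 * max(nrm, 1)
  if (any(tiny)) {
    if (any(u[tiny] < -1e-9 * max(abs(u), 1)))
      return(list(b = NULL, radius = -Inf))
    A <- A[!tiny, , drop = FALSE]
    u <- u[!tiny]
    nrm <- nrm[!tiny]
  }
  An <- A / nrm
  ## b = B (z - 1), z >= 0; maximize rho with radius = B rho
  Alp <- cbind(An, 1)
  blp <- (u / nrm + drop(An %*% rep(B, d))) / B
  cc <- c(rep(0, d), 1)
  sol <- tryCatch(
    boot::simplex(a = cc, A1 = Alp, b1 = blp, maxi = TRUE,
                  n.iter = 50L * (nrow(Alp) + d + 1L)),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved == -1 || any(!is.finite(sol$soln)))
    return(NULL)
  if (sol$solved == 0)                     # infeasible phase-1
    return(list(b = NULL, radius = -Inf))
  list(b = unname(B * (sol$soln[seq_len(d)] - 1)),
       radius = unname(B * sol$soln[d + 1L]))
}

## penalized fallback: minimize squared hinge violations from a start point
.penalty.point <- function(A, u, d, start = rep(0, d)) {
  f <- function(b) sum(pmax(drop(A %*% b) - u, 0)^2)
  g <- function(b) {
    viol <- pmax(drop(A %*% b) - u, 0)
    drop(2 * crossprod(A, viol))
  }
  opt <- stats::optim(start, f, g, method = "BFGS",
                      control = list(maxit = 500))
  opt$par
}

## push a near-feasible point strictly inside by cyclic over-projection onto
## the margin-shrunk half-spaces (the shrunk system is consistent: the exact
## Chebyshev center satisfies it, so projections converge)
.polish.interior <- function(A, u, x, radius) {
  nrm2 <- rowSums(A^2)
  ut <- u - 0.25 * radius * sqrt(nrm2)
  for (it in seq_len(2000)) {
    v <- drop(A %*% x) - ut
    i <- which.max(v)
    if (v[i] <= 0) break
    x <- x - A[i, ] * (v[i] / nrm2[i]) * 1.1
  }
  x
}

#' Find a strictly interior point of the flux space
#'
#' Solves the Chebyshev-center linear program (the point maximizing the
#' minimal distance to the constraint hyperplanes) with a simplex solver.
#' The result classifies the space as `"interior"` (a strictly feasible
#' point exists), `"degenerate"` (feasible but lower-dimensional: the
#' maximal inscribed radius is ~0) or `"empty"`.  An empty space means the
#' observed data are incompatible with the model: no stoichiometrically
#' balanced flux profile lies within the stated bounds.
#'
#' @param space a [FluxSpace].
#' @param tol radius below which the space is reported degenerate.
#' @return list with `status`, `point` (basis coordinates, or `NULL`) and
#'   `radius`.
#' @export
findInteriorPoint <- function(space, tol = 1e-9) {
  A <- space@A
  u <- space@u
  d <- ncol(A)
  B <- max(abs(u)) + 1
  sol <- .chebyshev.lp(A, u, B)
  if (is.null(sol)) {
    ## LP solver failed: try a penalty descent, then classify by feasibility
    b <- .penalty.point(A, u, d)
    slack <- u - drop(A %*% b)
    if (min(slack) > tol)
      return(list(status = "interior", point = b, radius = min(slack)))
    if (min(slack) > -1e-7)
      return(list(status = "degenerate", point = b, radius = max(min(slack), 0)))
    return(list(status = "empty", point = NULL, radius = NA_real_))
  }
  if (is.infinite(sol$radius) && sol$radius < 0)
    return(list(status = "empty", point = NULL, radius = NA_real_))
  if (sol$radius <= tol) {
    slack <- u - drop(A %*% sol$b)
    if (min(slack) < -1e-7)
      return(list(status = "empty", point = NULL, radius = NA_real_))
    return(list(status = "degenerate", point = sol$b, radius = max(sol$radius, 0)))
  }
  b <- sol$b
  ## simplex solutions sit on binding constraints up to solver tolerance;
  ## nudge strictly inside before handing the point to a sampler
  if (min(u - drop(A %*% b)) <= 0) {
    b <- .polish.interior(A, u, b, sol$radius)
    if (min(u - drop(A %*% b)) <= 0)
      return(list(status = "degenerate", point = sol$b,
                  radius = max(sol$radius, 0)))
  }
  list(status = "interior", point = b, radius = sol$radius)
}

#' Map basis points to balanced flux profiles
#'
#' The exact linear map `v = K b`.  Each resulting flux vector satisfies
#' `S v = 0` to machine precision because the columns of `K` span the
#' nullspace of `S`.
#'
#' @param K nullspace basis.
#' @param points numeric vector (one basis point) or matrix with one basis
#'   point per row.
#' @return numeric vector or matrix (points x reactions).
#' @export
basisToFluxes <- function(K, points) {
  if (is.matrix(points)) points %*% t(K) else drop(K %*% points)
}
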