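#' @include AllClasses.R
NULL

## crude effective sample size from the initial positive autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

.sample.checks <- function(space, start) {
  if (is.null(start)) {
    ip <- findInteriorPoint(space)
    if (ip$status != "interior")
      stop("flux space is ", ip$status,
           ": the observed data do not fit the specified model",
           call. = FALSE)
    start <- ip$point
  }
  slack <- space@u - drop(space@A %*% start)
  if (min(slack) <= 0)
    stop("starting point is not strictly interior", call. = FALSE)
  start
}

.new.sample <- function(space, pts, algorithm, diagnostics, seed) {
  flx <- pts %*% t(space@K)
  colnames(flx) <- space@reactionNames
  diagnostics$ess <- apply(pts, 2, .ess)
  methods::new("BalancedFluxSample", basisPoints = pts, fluxes = flx,
               algorithm = algorithm, diagnostics = diagnostics,
               seed = as.integer(seed))
}

#' Hit-and-run sampling of the balanced-flux polytope
#'
#' The random-direction algorithm: from the current interior point, draw a
#' uniformly random direction, intersect the line with the polytope
#' `A b <= u` to get a chord, and jump to a uniform point on the chord.
#' The stationary distribution is uniform over the polytope.  Numerically
#' zero-length chords cause the direction to be resampled (counted in the
#' diagnostics).
#'
#' @param space a [FluxSpace].
#' @param n number of samples to keep.
#' @param burnIn steps discarded before recording.
#' @param thin keep every `thin`-th step.
#' @param seed integer seed (recorded in the result).
#' @param start optional strictly interior starting basis point; default is
#'   the Chebyshev center from [findInteriorPoint()].
#' @return A [BalancedFluxSample].
#' @export
sampleHitAndRun <- function(space, n, burnIn = 1000, thin = 10, seed = 1,
                            start = NULL) {
  set.seed(seed)
  x <- .sample.checks(space, start)
  A <- space@A
  u <- space@u
  d <- ncol(A)
  pts <- matrix(0, nrow = n, ncol = d)
  kept <- 0L
  step <- 0L
  degenerate <- 0L
  total <- burnIn + n * thin
  while (kept < n) {
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    ad <- drop(A %*% dir)
    slack <- u - drop(A %*% x)
    tmax <- suppressWarnings(min(slack[ad > 1e-14] / ad[ad > 1e-14]))
    tmin <- suppressWarnings(max(slack[ad < -1e-14] / ad[ad < -1e-14]))
    if (!is.finite(tmax) || !is.finite(tmin) || tmax - tmin < 1e-13) {
      degenerate <- degenerate + 1L
      if (degenerate > 100L * total)
        stop("hit-and-run cannot find a usable chord; polytope may be ",
             "degenerate", call. = FALSE)
      next
    }
    x <- x + stats::runif(1, tmin, tmax) * dir
    step <- step + 1L
    if (step > burnIn && ((step - burnIn) %% thin == 0L)) {
      kept <- kept + 1L
      pts[kept, ] <- x
    }
  }
  .new.sample(space, pts, "hit-and-run",
              list(degenerate_chords = degenerate, burn_in = burnIn,
                   thin = thin), seed)
}

#' Mirror sampling of the balanced-flux polytope
#'
#' Gaussian random-walk proposals reflected off violated constraint
#' hyperplanes until the point lies inside the polytope; reflection
#' preserves the uniform stationary distribution and tends to give more
#' even coverage than hit-and-run at the cost of speed.  Proposals still
#' violating constraints after `maxBounce` reflections are rejected and
#' logged.
#'
#' @param space a [FluxSpace].
#' @param n number of samples to keep.
#' @param step proposal standard deviation; default `0.1 * mean slack` of
#'   the starting point (scales with the polytope).
#' @param seed integer seed.
#' @param burnIn,thin chain settings as in [sampleHitAndRun()].
#' @param maxBounce maximum reflections per proposal.
#' @param start optional strictly interior starting basis point.
#' @return A [BalancedFluxSample].
#' @export
sampleMirror <- function(space, n, step = NULL, seed = 1, burnIn = 1000,
                         thin = 10, maxBounce = 50, start = NULL) {
  set.seed(seed)
  x <- .sample.checks(space, start)
  A <- space@A
  u <- space@u
  d <- ncol(A)
  nrm2 <- rowSums(A^2)
  if (is.null(step))
    step <- 0.1 * mean((space@u - drop(space@A %*% x)) / sqrt(nrm2))
  pts <- matrix(0, nrow = n, ncol = d)
  kept <- 0L
  it <- 0L
  rejected <- 0L
  bounces <- 0L
  while (kept < n) {
    it <- it + 1L
    prop <- x + stats::rnorm(d, sd = step)
    ok <- TRUE
    for (bounce in seq_len(maxBounce)) {
      viol <- drop(A %*% prop) - u
      i <- which.max(viol)
      if (viol[i] <= 0) break
      bounces <- bounces + 1L
      prop <- prop - 2 * (viol[i] / nrm2[i]) * A[i, ]
      if (bounce == maxBounce) ok <- FALSE
    }
    if (ok && any(drop(A %*% prop) - u > 0)) ok <- FALSE
    if (ok) x <- prop else rejected <- rejected + 1L
    if (it > burnIn && ((it - burnIn) %% thin == 0L)) {
      kept <- kept + 1L
      pts[kept, ] <- x
    }
  }
  .new.sample(space, pts, "mirror",
              list(rejected_steps = rejected, reflections = bounces,
                   step = step, burn_in = burnIn, thin = thin), seed)
}

#' Write / read sampled flux profiles
#'
#' `writeFluxSample` writes the flux matrix as TSV (header = reaction names)
#' and the chain diagnostics as JSON next to it (`<path>.diagnostics.json`).
#'
#' @param sample a [BalancedFluxSample].
#' @param path output TSV path.
#' @return `path`, invisibly (`readFluxSample` returns the flux matrix).
#' @export
writeFluxSample <- function(sample, path) {
  utils::write.table(as.data.frame(sample@fluxes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(sample@diagnostics, list(algorithm = sample@algorithm,
                               seed = sample@seed)),
    paste0(path, ".diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFluxSample
#' @export
readFluxSample <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}
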