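#' @include AllClasses.R
NULL

## random sparse internal reaction column: >=1 reactant, >=1 product;
## species not yet used by any internal reaction are picked first so that
## no species ends up touched only by its exchange (which would force that
## exchange flux to zero at steady state)
.random.reaction <- function(nSpecies, uncovered = integer()) {
  k <- sample(2:min(3, nSpecies), 1)
  take <- min(length(uncovered), k)
  sp <- if (take > 0)
    uncovered[sample.int(length(uncovered), take)] else integer()
  if (take < k)
    sp <- c(sp, sample(setdiff(seq_len(nSpecies), sp), k - take))
  sp <- sample(sp)                          # randomize reactant/product roles
  col <- numeric(nSpecies)
  nReact <- sample.int(k - 1L, 1)
  coefs <- sample(c(1, 1, 2), k, replace = TRUE)
  col[sp[seq_len(nReact)]] <- -coefs[seq_len(nReact)]
  col[sp[-seq_len(nReact)]] <- coefs[-seq_len(nReact)]
  col
}

#' Generate a synthetic stoichiometric network with known true fluxes
#'
#' Builds a random sparse integer stoichiometry with a guaranteed nontrivial
#' nullspace: `nExchange` transport reactions (one species each, written in
#' the uptake direction, assigned round-robin so species coverage is even)
#' plus random internal conversions of 2-3 species.  The transport reactions
#' form the observed subset, giving an overdetermined partition
#' (`n_b >= n_c + 2` is enforced).  A ground-truth flux vector is obtained
#' by projecting a target vector with log-uniform magnitudes spanning
#' `fluxRange` (default 0.1-400 nmol/1e6 cells/h, about three decades) onto
#' the nullspace, so `S v = 0` holds to machine precision while the flux
#' magnitudes mirror a realistic rank spread.
#'
#' The candidate network is regenerated (deterministically under `seed`)
#' until the structural requirements hold: nontrivial nullspace, full
#' column rank of the calculated block, and no all-zero rows.
#'
#' @param nSpecies number of balanced species.
#' @param nReactions total reactions (exchanges + internal).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param nExchange number of observed transport reactions (default
#'   `min(nSpecies, ceiling(2/3 * nReactions))`).
#' @param cv observation coefficient of variation (fraction) used for the
#'   noise specification of the observed fluxes.
#' @param fluxRange magnitude range for the true fluxes.
#' @return A [ToyScenario].
#' @export
makeToyNetwork <- function(nSpecies = 8, nReactions = 12, seed = 1,
                           nExchange = NULL, cv = 0.1,
                           fluxRange = c(0.1, 400)) {
  set.seed(seed)
  if (is.null(nExchange))
    nExchange <- min(nSpecies, ceiling(2 / 3 * nReactions))
  nInternal <- nReactions - nExchange
  if (nInternal < 1L)
    stop("need at least one internal (calculated) reaction", call. = FALSE)
  if (nSpecies < nInternal + 2L)
    stop("shape is not overdetermined: need nSpecies >= internal + 2",
         call. = FALSE)
  exch <- matrix(0, nSpecies, nExchange)
  for (j in seq_len(nExchange))
    exch[(j - 1L) %% nSpecies + 1L, j] <- 1     # uptake direction
  for (attempt in seq_len(200)) {
    internal <- matrix(0, nSpecies, nInternal)
    for (j in seq_len(nInternal)) {
      uncovered <- which(rowSums(abs(internal)) == 0)
      internal[, j] <- .random.reaction(nSpecies, uncovered)
    }
    S <- cbind(internal, exch)
    ok <- qr(internal)$rank == nInternal &&
      qr(S)$rank < ncol(S) &&
      all(rowSums(abs(S)) > 0)
    if (ok) {
      ## no reaction may be structurally forced to zero flux (all-zero row
      ## of the nullspace basis): such a network cannot carry the intended
      ## magnitude spread
      K0 <- nullspaceBasis(S)
      ok <- ncol(K0) > 0 && all(rowSums(K0^2) > 1e-12)
    }
    if (ok) break
    if (attempt == 200)
      stop("requested shape admits no usable network; increase nSpecies ",
           "or nReactions", call. = FALSE)
  }
  rxn <- c(sprintf("R%d", seq_len(nInternal)),
           sprintf("up_%s", sprintf("S%d", ((seq_len(nExchange) - 1L) %% nSpecies) + 1L)))
  rxn <- make.unique(rxn, sep = "_")
  model <- .StoichiometricModel(S, sprintf("S%d", seq_len(nSpecies)), rxn,
                                rep(FALSE, ncol(S)))
  K <- nullspaceBasis(S)
  nr <- ncol(S)
  ## redraw the target until every projected flux stays inside the intended
  ## magnitude window (the projection can otherwise produce near-zero fluxes,
  ## which make relative noise and band constraints degenerate)
  v <- NULL
  for (draw in seq_len(500)) {
    target <- sample(c(-1, 1), nr, TRUE) *
      10^stats::runif(nr, log10(fluxRange[1]), log10(fluxRange[2]))
    cand <- drop(K %*% crossprod(K, target))
    cand <- cand * fluxRange[2] / max(abs(cand))
    if (min(abs(cand)) >= fluxRange[1]) {
      v <- cand
      break
    }
  }
  if (is.null(v))
    stop("could not find a flux profile spanning the requested magnitude ",
         "range on this topology; try another seed", call. = FALSE)
  names(v) <- rxn
  observed <- rxn[seq.int(nInternal + 1L, nr)]
  obs <- methods::new("ObservedFluxes",
                      values = v[observed], sd = cv * abs(v[observed]))
  methods::new("ToyScenario", model = model, trueFluxes = v,
               observed = observed, obs = obs, cv = cv,
               seed = as.integer(seed))
}

#' Derive a mis-specified fitting scenario
#'
#' Data are generated from the base scenario, but the fitting model omits
#' one (calculated) reaction: fits of such data exhibit lack of fit, the
#' situation the balanced-flux comparison is designed to expose.  Deleting a
#' reaction whose true flux is (near) zero produces no degradation.
#'
#' @param base a [ToyScenario].
#' @param deletedReaction name of the reaction to remove from the fitting
#'   model (must not be an observed reaction).
#' @return A [ToyScenario] whose `model` lacks the reaction and whose
#'   `trueFluxes` keep the base profile for the remaining reactions.  The
#'   observed fluxes are identical to the base scenario's.  Note the reduced
#'   model does not balance the retained truth -- that mismatch is the
#'   purpose of the construction, so the usual balance validity does not
#'   apply to this object.
#' @export
makeMisfitScenario <- function(base, deletedReaction) {
  if (deletedReaction %in% base@observed)
    stop("cannot delete an observed reaction", call. = FALSE)
  model2 <- removeReaction(base@model, deletedReaction)
  keep <- setdiff(names(base@trueFluxes), deletedReaction)
  v2 <- base@trueFluxes[keep]
  sc <- methods::new("ToyScenario", model = base@model,   # placeholder
                     trueFluxes = base@trueFluxes, observed = base@observed,
                     obs = base@obs, cv = base@cv, seed = base@seed)
  ## bypass the balance validity check: the reduced model deliberately does
  ## NOT balance the base truth -- that is the point
  sc@model <- model2
  sc@trueFluxes <- v2
  sc
}

#' Simulate metabolite and cell-density timecourses from a scenario
#'
#' Integrates the extracellular balance `dC_i/dt = -v_i X(t)` (uptake
#' positive) for each observed transport flux, with exponential cell growth
#' `X(t) = X0 exp(mu t)`, then adds Gaussian measurement noise.  Initial
#' concentrations are chosen large enough that consumed metabolites stay
#' positive over the grid.  The result feeds the timecourse-to-flux module:
#' with zero noise, [fluxTable()] recovers the scenario's observed fluxes at
#' interior times up to spline bias.
#'
#' @param scenario a [ToyScenario].
#' @param tGrid sampling times (h).
#' @param noiseCV relative measurement noise (fraction of each series'
#'   dynamic range) added to concentrations and density.
#' @param X0 initial cell density (1e6 cells/mL).
#' @param mu specific growth rate (1/h).
#' @param seed integer seed.
#' @return `data.frame` with columns `time_h`, `series`, `value`; cell
#'   density appears as series `"X"`.
#' @export
makeTimecourse <- function(scenario, tGrid = seq(0, 96, by = 8),
                           noiseCV = 0, X0 = 0.3, mu = 0.03, seed = 1) {
  set.seed(seed)
  X <- X0 * exp(mu * tGrid)
  cumCells <- X0 * (exp(mu * tGrid) - 1) / mu   # integral of X dt
  out <- list()
  for (nm in scenario@observed) {
    v <- scenario@trueFluxes[[nm]]
    C <- -v * cumCells                          # uptake positive: C falls
    C0 <- max(0, -min(C)) * 1.2 + 0.1 * max(abs(C), 1)
    C <- C0 + C
    sdn <- noiseCV * diff(range(C))
    out[[nm]] <- data.frame(time_h = tGrid, series = nm,
                            value = C + stats::rnorm(length(C), sd = sdn))
  }
  sdX <- noiseCV * diff(range(X))
  out$X <- data.frame(time_h = tGrid, series = "X",
                      value = X + stats::rnorm(length(X), sd = sdX))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
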