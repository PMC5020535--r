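#' @include AllClasses.R
NULL

#' Remove species balances from a model
#'
#' Deletes the balance rows for the named species, the standard way of
#' excluding unbalanced cofactors and byproducts (O2, CO2, ATP, NADH, NADPH,
#' FADH) before flux analysis.  Reactions whose column becomes all-zero are
#' reported by name in a warning and dropped, so the returned model stays
#' structurally valid; nothing is removed silently.
#'
#' @param model a [StoichiometricModel].
#' @param names character vector of species to remove.
#' @return A [StoichiometricModel] without those balances.
#' @seealso [addSpecies()] for the inverse operation.
#' @export
removeSpecies <- function(model, names) {
  if (length(names) == 0L) return(model)
  missing <- setdiff(names, model@species)
  if (length(missing))
    stop("species not in model: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- !(model@species %in% names)
  S <- model@S[keep, , drop = FALSE]
  zero <- colSums(abs(S)) == 0
  if (any(zero)) {
    warning("removal left reaction(s) with no balanced species; dropped: ",
            paste(model@reactions[zero], collapse = ", "))
    S <- S[, !zero, drop = FALSE]
    return(.StoichiometricModel(S, model@species[keep],
                                model@reactions[!zero],
                                model@reversible[!zero]))
  }
  .StoichiometricModel(S, model@species[keep], model@reactions,
                       model@reversible)
}

#' Add a species balance to a model
#'
#' Appends one balance row, e.g. to re-introduce a cofactor such as NADH or
#' NADPH and assume it balanced by the defined stoichiometry (the
#' "re-balance species" workflow used to probe the effect of model
#' structure).
#'
#' @param model a [StoichiometricModel].
#' @param name new species identifier.
#' @param coefficients numeric vector of net stoichiometric coefficients for
#'   the new species, one per reaction (model order).
#' @return A [StoichiometricModel] with the extra balance.
#' @export
addSpecies <- function(model, name, coefficients) {
  if (length(coefficients) != length(model@reactions))
    stop("coefficients must have one entry per reaction (",
         length(model@reactions), ")", call. = FALSE)
  if (name %in% model@species)
    stop("species '", name, "' already in model", call. = FALSE)
  S <- rbind(model@S, as.numeric(coefficients))
  .StoichiometricModel(S, c(model@species, name), model@reactions,
                       model@reversible)
}

#' Remove a reaction from a model
#'
#' Drops one reaction column; used e.g. to construct deliberately
#' mis-specified fitting models (see [makeMisfitScenario()]).
#'
#' @param model a [StoichiometricModel].
#' @param name reaction identifier.
#' @return A [StoichiometricModel] without that reaction.
#' @export
removeReaction <- function(model, name) {
  j <- match(name, model@reactions)
  if (is.na(j))
    stop("reaction not in model: ", name, call. = FALSE)
  .StoichiometricModel(model@S[, -j, drop = FALSE], model@species,
                       model@reactions[-j], model@reversible[-j])
}

#' Partition a model into calculated and observed flux blocks
#'
#' Splits the stoichiometry column-wise into `S = [S_c | S_o]`: the named
#' reactions are the observed (measured) fluxes, everything else is to be
#' calculated by regression.  Column order within each block follows the
#' original model order.  An error is raised if `S_c` has more columns than
#' rows: the system would be underdetermined and no unique flux profile
#' could be calculated (note that an apparently determined `S_c` can still
#' hide non-identifiable fluxes if a key metabolite is unobserved; check
#' [conditionNumber()] and the fit rank).
#'
#' @param model a [StoichiometricModel].
#' @param observed character vector of observed reaction names.
#' @return A [FluxPartition].
#' @export
partitionModel <- function(model, observed) {
  missing <- setdiff(observed, model@reactions)
  if (length(missing))
    stop("unknown observed reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  obsIdx <- which(model@reactions %in% observed)
  calcIdx <- setdiff(seq_along(model@reactions), obsIdx)
  Sc <- model@S[, calcIdx, drop = FALSE]
  So <- model@S[, obsIdx, drop = FALSE]
  if (ncol(Sc) == 0L)
    warning("all reactions observed: nothing to calculate")
  if (ncol(Sc) > nrow(Sc))
    stop(sprintf(paste0(
      "underdetermined partition: %d calculated fluxes but only %d balances; ",
      "observe more fluxes or pool pathways"), ncol(Sc), nrow(Sc)),
      call. = FALSE)
  methods::new("FluxPartition",
               Sc = Sc, So = So,
               calcNames = model@reactions[calcIdx],
               obsNames = model@reactions[obsIdx],
               calcIdx = as.integer(calcIdx), obsIdx = as.integer(obsIdx))
}

#' Condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value.  Applied to the
#' reduced stoichiometry matrix `S_c` as a classical diagnostic: values
#' above ~1000 signal near-singularity and poorly determined fluxes.
#'
#' @param M numeric matrix.
#' @param rtol singular values below `rtol * max(singular value)` are treated
#'   as zero (rank deficiency), in which case `Inf` is returned with a
#'   warning.
#' @return A scalar (possibly `Inf`).
#' @export
conditionNumber <- function(M, rtol = 1e-10) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (length(d) == 0L || max(d) == 0) {
    warning("zero matrix: condition number undefined, returning Inf")
    return(Inf)
  }
  dmin <- d[min(dim(M))]
  if (is.na(dmin) || dmin < rtol * d[1]) {
    warning("rank-deficient matrix: condition number is Inf")
    return(Inf)
  }
  d[1] / dmin
}

#' Orthonormal nullspace basis of a stoichiometric matrix
#'
#' Computes `K` with orthonormal columns spanning `{v : S v = 0}` via the
#' singular value decomposition; singular values below
#' `rtol * max(singular value)` are treated as zero so the nullspace
#' dimension is reproducible under floating-point noise.  Any basis vector
#' `b` then yields a balanced flux profile `v = K b` (see [basisToFluxes()]).
#'
#' @param S numeric matrix (typically the full stoichiometry).
#' @param rtol relative singular-value tolerance.
#' @return Matrix `K` (ncol(S) rows); zero columns with a warning when the
#'   nullspace is trivial, i.e. the model admits no nonzero steady-state
#'   flux.
#' @export
nullspaceBasis <- function(S, rtol = 1e-10) {
  n <- ncol(S)
  if (n == 0L) return(matrix(0, 0, 0))
  sv <- svd(S, nu = 0, nv = n)
  d <- sv$d
  rank <- sum(d > rtol * max(d, 0))
  if (rank >= n) {
    warning("trivial nullspace: model admits no nonzero steady-state flux")
    return(matrix(0, nrow = n, ncol = 0))
  }
  sv$v[, seq.int(rank + 1L, n), drop = FALSE]
}
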