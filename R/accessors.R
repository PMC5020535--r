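#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setMethod("stoichiometry", "StoichiometricModel", function(object, ...) {
  S <- object@S
  dimnames(S) <- list(object@species, object@reactions)
  S
})

#' @rdname accessors
#' @export
setMethod("speciesNames", "StoichiometricModel", function(object, ...) object@species)

#' @rdname accessors
#' @export
setMethod("reactionNames", "StoichiometricModel", function(object, ...) object@reactions)

#' @rdname accessors
#' @export
setMethod("reversible", "StoichiometricModel", function(object, ...) {
  structure(object@reversible, names = object@reactions)
})

#' @rdname accessors
#' @export
setMethod("calcNames", "FluxPartition", function(object, ...) object@calcNames)

#' @rdname accessors
#' @export
setMethod("obsNames", "FluxPartition", function(object, ...) object@obsNames)

#' @rdname accessors
#' @export
setMethod("nBalances", "FluxPartition", function(object, ...) nrow(object@Sc))

#' @rdname accessors
#' @export
setMethod("nCalculated", "FluxPartition", function(object, ...) ncol(object@Sc))

#' @rdname accessors
#' @export
setMethod("fluxValues", "ObservedFluxes", function(object, ...) object@values)

#' @rdname accessors
#' @export
setMethod("fluxSD", "ObservedFluxes", function(object, ...) {
  structure(object@sd, names = names(object@values))
})

#' @rdname accessors
#' @export
setMethod("fluxes", "BalancedFluxSample", function(object, ...) object@fluxes)

#' @rdname accessors
#' @export
setMethod("basisPoints", "BalancedFluxSample", function(object, ...) object@basisPoints)

#' @rdname accessors
#' @export
setMethod("whiteningMatrix", "NoiseModel", function(object, ...) object@Pinv)

#' @rdname accessors
#' @export
setMethod("estimates", "GLSFit", function(object, ...) object@vHat)

#' @rdname accessors
#' @export
setMethod("nonsigPct", "SimulationResult", function(object, ...) object@nonsigPct)

#' @rdname accessors
#' @export
setMethod("chi2RejectPct", "SimulationResult", function(object, ...) object@chi2RejectPct)

## show methods -------------------------------------------------------------

setMethod("show", "StoichiometricModel", function(object) {
  cat("StoichiometricModel:", length(object@species), "species x",
      length(object@reactions), "reactions\n")
  nrev <- sum(object@reversible)
  cat("  reversible reactions:", nrev, "\n")
  cat("  species:  ", paste(utils::head(object@species, 6), collapse = ", "),
      if (length(object@species) > 6) "..." else "", "\n")
  cat("  reactions:", paste(utils::head(object@reactions, 6), collapse = ", "),
      if (length(object@reactions) > 6) "..." else "", "\n")
})

setMethod("show", "FluxPartition", function(object) {
  cat("FluxPartition:", nrow(object@Sc), "balances;",
      ncol(object@Sc), "calculated /", ncol(object@So), "observed fluxes\n")
  cat("  redundancy (n_b - n_c):", nrow(object@Sc) - ncol(object@Sc), "\n")
})

setMethod("show", "ObservedFluxes", function(object) {
  cat("ObservedFluxes:", length(object@values),
      "fluxes (nmol/1e6 cells/h; consumption positive)\n")
  cv <- ifelse(object@values != 0, 100 * object@sd / abs(object@values), NA)
  cat("  median |flux|:", signif(stats::median(abs(object@values)), 4),
      "  median CV:", signif(stats::median(cv, na.rm = TRUE), 3), "%\n")
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel:", nrow(object@V), "balances; jitter =",
      format(object@jitter[1], digits = 3), "\n")
})

setMethod("show", "GLSFit", function(object) {
  cat("GLSFit:", object@nc, "calculated fluxes from", object@nb,
      "balances (df =", object@df, ")\n")
  cat("  sigma2Hat =", signif(object@sigma2Hat, 4),
      " (should be ~1 under a correct model and covariance)\n")
  nsig <- sum(abs(object@tStat) >= stats::qt(0.975, object@df))
  cat("  fluxes significant at alpha = 0.05:", nsig, "of", object@nc, "\n")
})

setMethod("show", "FluxSpace", function(object) {
  cat("FluxSpace: basis dimension", ncol(object@K), "over",
      nrow(object@K), "reactions;", nrow(object@A), "inequalities\n")
  cat("  constrained observed fluxes:", length(object@obsRows),
      " (band multiplier a =", signif(object@a, 4), ")\n")
})

setMethod("show", "BalancedFluxSample", function(object) {
  cat("BalancedFluxSample:", nrow(object@fluxes), "profiles x",
      ncol(object@fluxes), "reactions (", object@algorithm, ")\n")
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nProfiles, "profiles x", object@mNoise,
      "noise replicates; noise =", object@noiseSource,
      if (object@noiseSource == "cv") paste0("(", 100 * object@cv, " %)") else "",
      "; alpha =", object@alpha, "\n")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", nrow(object@errPct), "replicates,",
      length(object@calcNames), "calculated fluxes\n")
  cat("  chi-square rejection:", signif(object@chi2RejectPct, 3), "%\n")
  cat("  mean non-significance:", signif(mean(object@nonsigPct), 3), "%\n")
  cat("  mean sigma2Hat:", signif(mean(object@sigma2), 4), "\n")
})

setMethod("show", "SmoothFit", function(object) {
  cat("SmoothFit:", object@nBasis, "cubic basis functions over t in [",
      min(object@t), ",", max(object@t), "];",
      length(object@t), "points; residual var =",
      signif(object@residualVar, 4), "\n")
})

setMethod("show", "ToyScenario", function(object) {
  cat("ToyScenario:", length(object@model@species), "species,",
      length(object@model@reactions), "reactions;",
      length(object@observed), "observed\n")
  cat("  |flux| range:", signif(min(abs(object@trueFluxes)), 3), "-",
      signif(max(abs(object@trueFluxes)), 3), "nmol/1e6 cells/h\n")
})
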