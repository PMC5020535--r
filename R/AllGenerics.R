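#' Accessor generics
#'
#' Small family of accessor generics for the core classes.  Accessors are the
#' supported way to read object contents; slots are implementation detail.
#'
#' @param object,x An object of one of the package classes.
#' @param ... Passed to methods.
#' @return The component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object, ...) standardGeneric("stoichiometry"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object, ...) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("reactionNames", function(object, ...) standardGeneric("reactionNames"))

#' @rdname accessors
#' @export
setGeneric("reversible", function(object, ...) standardGeneric("reversible"))

#' @rdname accessors
#' @export
setGeneric("calcNames", function(object, ...) standardGeneric("calcNames"))

#' @rdname accessors
#' @export
setGeneric("obsNames", function(object, ...) standardGeneric("obsNames"))

#' @rdname accessors
#' @export
setGeneric("nBalances", function(object, ...) standardGeneric("nBalances"))

#' @rdname accessors
#' @export
setGeneric("nCalculated", function(object, ...) standardGeneric("nCalculated"))

#' @rdname accessors
#' @export
setGeneric("fluxValues", function(object, ...) standardGeneric("fluxValues"))

#' @rdname accessors
#' @export
setGeneric("fluxSD", function(object, ...) standardGeneric("fluxSD"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object, ...) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("basisPoints", function(object, ...) standardGeneric("basisPoints"))

#' @rdname accessors
#' @export
setGeneric("whiteningMatrix", function(object, ...) standardGeneric("whiteningMatrix"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(object, ...) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("nonsigPct", function(object, ...) standardGeneric("nonsigPct"))

#' @rdname accessors
#' @export
setGeneric("chi2RejectPct", function(object, ...) standardGeneric("chi2RejectPct"))
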