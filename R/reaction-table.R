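#' @include AllClasses.R
NULL

## internal constructor
.StoichiometricModel <- function(S, species, reactions, reversible) {
  dimnames(S) <- NULL
  methods::new("StoichiometricModel",
               S = S, species = species, reactions = reactions,
               reversible = reversible)
}

#' Build a stoichiometric model from components
#'
#' Low-level constructor used by the readers and by tests.
#'
#' @param S species x reaction coefficient matrix (products positive).
#' @param species,reactions identifier vectors; taken from `dimnames(S)` when
#'   missing.
#' @param reversible logical per-reaction flags (default all irreversible).
#' @return A [StoichiometricModel].
#' @export
stoichiometricModel <- function(S, species = rownames(S),
                                reactions = colnames(S),
                                reversible = rep(FALSE, ncol(S))) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  .StoichiometricModel(S, as.character(species), as.character(reactions),
                       as.logical(reversible))
}

.parse.side <- function(side, line, lineno) {
  side <- trimws(side)
  if (side == "")
    return(list(species = character(), coef = numeric()))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  sp <- character(length(terms))
  cf <- numeric(length(terms))
  for (k in seq_along(terms)) {
    tok <- strsplit(terms[k], "[[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1L) {
      cf[k] <- 1
      sp[k] <- tok
    } else if (length(tok) == 2L && !is.na(suppressWarnings(as.numeric(tok[1])))) {
      cf[k] <- as.numeric(tok[1])
      sp[k] <- tok[2]
    } else {
      stop(sprintf("line %d: cannot parse term '%s' in '%s'",
                   lineno, terms[k], line), call. = FALSE)
    }
  }
  list(species = sp, coef = cf)
}

#' Parse a plain-text reaction table
#'
#' The canonical model format: one reaction per line,
#' `name: [coef] species { + [coef] species } (->|<->) [coef] species {...}`,
#' with coefficients defaulting to 1 and `<->` marking reversible reactions.
#' Lines starting with `#` are comments; an optional header line
#' `external: A B C` lists species excluded from balancing (unbalanced
#' species such as O2, CO2 or ATP that the modeler removes before analysis).
#' A side may be empty to express pure exchange (e.g. `up_A: -> A`).
#'
#' Coefficients in the resulting matrix are net products-minus-reactants, so
#' columns are written products-positive.  A transport reaction written in
#' the uptake direction (`up_glc: -> Glc`) then carries a positive flux when
#' the species is consumed from the medium, matching the sign convention of
#' [ObservedFluxes].
#'
#' @param text character scalar (whole document) or vector of lines.
#' @return A [StoichiometricModel].
#' @seealso [readReactionTable()], [serializeReactionTable()]
#' @examples
#' m <- parseReactionTable("R1: A -> B\nR2: B -> C")
#' stoichiometry(m)
#' @export
parseReactionTable <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  external <- character()
  rxn_names <- character()
  rev_flags <- logical()
  contrib <- list()           # per reaction: named numeric of net coefficients
  species <- character()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (grepl("^external[[:space:]]*:", line)) {
      ext <- sub("^external[[:space:]]*:", "", line)
      external <- c(external, strsplit(trimws(ext), "[[:space:],]+")[[1]])
      next
    }
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0)
      stop(sprintf("line %d: missing 'name:' prefix in '%s'", i, line),
           call. = FALSE)
    name <- trimws(substr(line, 1, colon - 1))
    body <- trimws(substr(line, colon + 1, nchar(line)))
    if (name %in% rxn_names)
      stop(sprintf("line %d: duplicate reaction name '%s'", i, name),
           call. = FALSE)
    rev <- grepl("<->", body, fixed = TRUE)
    sides <- strsplit(body, if (rev) "<->" else "->", fixed = TRUE)[[1]]
    if (length(sides) > 2L || !grepl("->", body, fixed = TRUE))
      stop(sprintf("line %d: expected exactly one '->' or '<->' in '%s'",
                   i, line), call. = FALSE)
    if (length(sides) == 1L) sides <- c(sides, "")
    lhs <- .parse.side(sides[1], line, i)
    rhs <- .parse.side(sides[2], line, i)
    if (length(lhs$species) + length(rhs$species) == 0L)
      stop(sprintf("line %d: reaction '%s' references no species", i, name),
           call. = FALSE)
    net <- numeric()
    for (k in seq_along(lhs$species))
      net[lhs$species[k]] <- (if (lhs$species[k] %in% names(net))
        net[[lhs$species[k]]] else 0) - lhs$coef[k]
    for (k in seq_along(rhs$species))
      net[rhs$species[k]] <- (if (rhs$species[k] %in% names(net))
        net[[rhs$species[k]]] else 0) + rhs$coef[k]
    rxn_names <- c(rxn_names, name)
    rev_flags <- c(rev_flags, rev)
    contrib[[name]] <- net
    species <- union(species, names(net))
  }
  if (length(rxn_names) == 0L)
    stop("no reactions found", call. = FALSE)
  species <- setdiff(species, external)
  S <- matrix(0, nrow = length(species), ncol = length(rxn_names))
  for (j in seq_along(rxn_names)) {
    net <- contrib[[j]]
    keep <- intersect(names(net), species)
    if (length(keep) == 0L)
      stop(sprintf("reaction '%s' involves no balanced species", rxn_names[j]),
           call. = FALSE)
    S[match(keep, species), j] <- net[keep]
  }
  .StoichiometricModel(S, species, rxn_names, rev_flags)
}

#' Read a reaction table from a file
#'
#' @param path path to a UTF-8 reaction-table file (see [parseReactionTable()]
#'   for the format).
#' @return A [StoichiometricModel].
#' @export
readReactionTable <- function(path) {
  parseReactionTable(readLines(path, warn = FALSE))
}

#' Serialize a model back to the reaction-table format
#'
#' `parseReactionTable(serializeReactionTable(m))` reproduces the matrix of
#' `m` exactly (species order follows first appearance, so row order may
#' differ; coefficients are preserved).
#'
#' @param model a [StoichiometricModel].
#' @return character vector of lines.
#' @seealso [writeReactionTable()]
#' @export
serializeReactionTable <- function(model) {
  S <- model@S
  vapply(seq_along(model@reactions), function(j) {
    col <- S[, j]
    lhs <- which(col < 0)
    rhs <- which(col > 0)
    fmt <- function(idx, sgn) {
      paste(vapply(idx, function(i) {
        cf <- sgn * col[i]
        if (cf == 1) model@species[i]
        else paste(format(cf, trim = TRUE), model@species[i])
      }, character(1)), collapse = " + ")
    }
    arrow <- if (model@reversible[j]) "<->" else "->"
    paste0(model@reactions[j], ": ", fmt(lhs, -1), " ", arrow, " ", fmt(rhs, 1))
  }, character(1))
}

#' @rdname serializeReactionTable
#' @param path output file path.
#' @return `writeReactionTable` returns `path` invisibly.
#' @export
writeReactionTable <- function(model, path) {
  writeLines(serializeReactionTable(model), path)
  invisible(path)
}

#' Write a species-by-reaction summary table
#'
#' Writes the stoichiometric matrix as a TSV with species as rows and
#' reactions as columns, for inspection in a spreadsheet.
#'
#' @param model a [StoichiometricModel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeModelSummary <- function(model, path) {
  S <- stoichiometry(model)
  df <- data.frame(species = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
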