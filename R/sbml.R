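#' @include AllClasses.R
NULL

#' Read the stoichiometry of an SBML model (best-effort subset)
#'
#' Reads species, reactions and stoichiometric coefficients from an SBML
#' Level 2/3 document.  Only the network structure is consumed: kinetic laws,
#' parameters, rules and annotations are ignored.  Species flagged with
#' `boundaryCondition="true"` (and any listed in `external`) are excluded
#' from balancing, mirroring the removal of unbalanced species before
#' analysis.  The plain-text reaction table ([readReactionTable()]) is the
#' canonical format; this reader exists for interoperability.
#'
#' @param path path to an SBML file.
#' @param external additional species ids to exclude from balancing.
#' @return A [StoichiometricModel].
#' @export
readSBMLModel <- function(path, external = character()) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0L)
    stop("no species found in SBML document", call. = FALSE)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  boundary <- tolower(ifelse(is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")),
                             "false", xml2::xml_attr(sp_nodes, "boundaryCondition")))
  external <- union(external, sp_id[boundary == "true"])
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L)
    stop("no reactions found in SBML document", call. = FALSE)
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  rev <- tolower(ifelse(is.na(xml2::xml_attr(rx_nodes, "reversible")),
                        "true", xml2::xml_attr(rx_nodes, "reversible"))) == "true"
  balanced <- setdiff(sp_id, external)
  S <- matrix(0, nrow = length(balanced), ncol = length(rx_nodes))
  refs <- function(node, tag) {
    xml2::xml_find_all(node, sprintf(
      ".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
  }
  for (j in seq_along(rx_nodes)) {
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      rr <- refs(rx_nodes[[j]], tag)
      if (length(rr) == 0L) next
      ids <- xml2::xml_attr(rr, "species")
      st <- suppressWarnings(as.numeric(xml2::xml_attr(rr, "stoichiometry")))
      st[is.na(st)] <- 1
      for (k in seq_along(ids)) {
        i <- match(ids[k], balanced)
        if (!is.na(i)) S[i, j] <- S[i, j] + side * st[k]
      }
    }
  }
  zero <- colSums(abs(S)) == 0
  if (any(zero)) {
    warning("dropping reaction(s) with no balanced species: ",
            paste(rx_id[zero], collapse = ", "))
    S <- S[, !zero, drop = FALSE]
    rx_id <- rx_id[!zero]
    rev <- rev[!zero]
  }
  .StoichiometricModel(S, balanced, rx_id, rev)
}
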