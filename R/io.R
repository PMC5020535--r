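#' @include AllClasses.R
NULL

#' Read an observed-flux table
#'
#' Expects a TSV/CSV with a name column (`name` or `flux_name`, or the first
#' character column), a `flux` column (nmol/1e6 cells/h, consumption
#' positive) and either `sd` (same units) or `cv` (percent).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return An [ObservedFluxes].
#' @export
readObservedFluxes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  nameCol <- intersect(c("name", "flux_name"), names(df))
  if (length(nameCol) == 0L)
    nameCol <- names(df)[vapply(df, is.character, logical(1))][1]
  if (is.na(nameCol) || !"flux" %in% names(df))
    stop("need a name column and a 'flux' column", call. = FALSE)
  v <- df$flux
  names(v) <- df[[nameCol[1]]]
  if ("sd" %in% names(df)) observedFluxes(v, sd = df$sd)
  else if ("cv" %in% names(df)) observedFluxes(v, cv = df$cv)
  else stop("need an 'sd' or 'cv' column", call. = FALSE)
}

#' Write an observed-flux table
#'
#' TSV with columns `name`, `flux`, `sd`, `cv` (cv in percent, `NA` for
#' zero fluxes); round-trips through [readObservedFluxes()].
#'
#' @param obs an [ObservedFluxes].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeObservedFluxes <- function(obs, path) {
  v <- obs@values
  cv <- ifelse(v != 0, 100 * obs@sd / abs(v), NA)
  utils::write.table(
    data.frame(name = names(v), flux = unname(v), sd = obs@sd, cv = cv),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read timecourse data
#'
#' CSV with columns `time_h`, `series`, `value`; cell density uses series
#' `"X"`.  Returns a named list of `data.frame`s (one per series).
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return named list of data.frames with `time_h` and `value`.
#' @export
readTimecourses <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "series", "value") %in% names(df)))
  split(df[c("time_h", "value")], df$series)
}
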