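# Pathway atlas configuration and subject-table I/O.

#' Load pathway definitions from a YAML or JSON config
#'
#' Schema: \code{pathways: [{name, rois: [{name, laterality}]}]}. ROIs may
#' be shared across pathways (the amygdala, for instance, belongs to both
#' the mesolimbic and the Ch4 lateral capsular network) but must be unique
#' within a pathway.
#'
#' @param path config file; format chosen by extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return Named list of \linkS4class{Pathway} objects.
#' @examples
#' paths <- loadPathwayConfig(
#'   system.file("extdata", "pathways_default.yaml", package = "phnet"))
#' length(paths)
#' @export
loadPathwayConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("pathway config '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop(sprintf("unsupported pathway config extension '.%s' (use .yaml or .json)", ext)))
  if (!is.list(cfg) || is.null(cfg$pathways) || !length(cfg$pathways))
    stop("pathway config must contain a non-empty 'pathways' list")
  out <- lapply(cfg$pathways, function(p) {
    if (is.null(p$name) || is.null(p$rois))
      stop("each pathway entry needs 'name' and 'rois'")
    rois <- vapply(p$rois, function(r) as.character(r$name), character(1))
    lat <- vapply(p$rois, function(r)
      if (is.null(r$laterality)) "bilateral" else as.character(r$laterality),
      character(1))
    Pathway(p$name, rois, lat)
  })
  names(out) <- vapply(out, function(p) p@name, character(1))
  if (anyDuplicated(names(out)))
    stop("pathway names must be unique in the config")
  out
}

#' The seven shipped neurotransmitter pathway networks
#'
#' Two dopaminergic networks (striatocortical, mesolimbic) and five
#' cholinergic networks (Ch1--3, Ch4 medial, Ch4 lateral perisylvian,
#' Ch4 lateral capsular, Ch5--6), loaded from the packaged default config.
#'
#' @return Named list of seven \linkS4class{Pathway} objects.
#' @export
defaultPathways <- function() {
  loadPathwayConfig(system.file("extdata", "pathways_default.yaml",
                                package = "phnet", mustWork = TRUE))
}

#' Read a subject-by-ROI table
#'
#' Delimited UTF-8 text, header row of ROI names, one subject per row.
#' The delimiter is sniffed from the extension (\code{.csv} = comma,
#' \code{.tsv}/\code{.txt} = tab). Missing or non-numeric cells are an
#' error, never imputed.
#'
#' @param path file to read.
#' @param groupLabel diagnostic group label to attach.
#' @return An \linkS4class{UptakeMatrix}.
#' @export
readSubjectTable <- function(path, groupLabel = "group") {
  if (!file.exists(path))
    stop(sprintf("subject table '%s' does not exist", path))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)))
    stop(sprintf("duplicate column name(s): %s",
                 paste(unique(names(df)[duplicated(names(df))]),
                       collapse = ", ")))
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    raw <- trimws(df[[j]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !nzchar(raw))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad[1], names(df)[j]))
    vals[, j] <- num
  }
  UptakeMatrix(vals, groupLabel = groupLabel)
}

#' Write a subject-by-ROI table
#'
#' Writes comma- or tab-delimited text (by extension) with a header row of
#' ROI names and full double precision, so
#' \code{readSubjectTable(writeSubjectTable(x))} round-trips bit-identically.
#'
#' @param x an \linkS4class{UptakeMatrix}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeSubjectTable <- function(x, path) {
  stopifnot(is(x, "UptakeMatrix"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  vals <- uptakeValues(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(vals), collapse = sep), con)
  for (i in seq_len(nrow(vals)))
    writeLines(paste(.fmtNum(vals[i, ]), collapse = sep), con)
  invisible(path)
}

#' Extract the columns of one pathway
#'
#' @param x an \linkS4class{UptakeMatrix} holding all ROIs.
#' @param pathway a \linkS4class{Pathway}; every ROI it lists must be
#'   present in \code{x}.
#' @return An \linkS4class{UptakeMatrix} restricted to the pathway's ROIs,
#'   in pathway order; subjects untouched.
#' @export
extractPathway <- function(x, pathway) {
  stopifnot(is(x, "UptakeMatrix"), is(pathway, "Pathway"))
  missing <- setdiff(pathway@rois, roiNames(x))
  if (length(missing))
    stop(sprintf("pathway '%s' lists ROI(s) absent from the table: %s",
                 pathway@name, paste(missing, collapse = ", ")))
  UptakeMatrix(uptakeValues(x)[, pathway@rois, drop = FALSE],
               groupLabel = groupLabel(x))
}
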