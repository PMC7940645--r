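# Group-level metabolic connectivity: Pearson correlation across subjects
# and the 1 - |r| distance transform seeding the filtration.

#' Pearson correlation network of a group
#'
#' Correlates every ROI pair across subjects. A zero-variance ROI would give
#' an undefined coefficient, so it is rejected by name rather than silently
#' producing NaN.
#'
#' @param x an \linkS4class{UptakeMatrix} (>= 3 subjects).
#' @return A \linkS4class{CorrelationMatrix}.
#' @examples
#' x <- UptakeMatrix(matrix(rnorm(30), 10, 3,
#'                          dimnames = list(NULL, c("a", "b", "c"))))
#' pearsonMatrix(x)
#' @export
pearsonMatrix <- function(x) {
  stopifnot(is(x, "UptakeMatrix"))
  vals <- uptakeValues(x)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance ROI(s): %s",
                 paste(colnames(vals)[sds == 0], collapse = ", ")))
  r <- stats::cor(vals)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  new("CorrelationMatrix", r = r, nSubjects = nrow(vals))
}

#' Correlation-to-distance transform
#'
#' The default transform is \eqn{d_{ij} = 1 - |r_{ij}|}: strong coupling of
#' either sign counts as proximity. The \code{"signed"} mode, provided for
#' sensitivity analyses, uses \eqn{d_{ij} = (1 - r_{ij})/2} so that
#' anticorrelation counts as distance while the values still span [0, 1]
#' and the unit filtration ceiling is preserved.
#'
#' @param x a \linkS4class{CorrelationMatrix}.
#' @param mode \code{"absolute"} (default) or \code{"signed"}.
#' @return A \linkS4class{DistanceMatrix} with zero diagonal.
#' @export
toDistance <- function(x, mode = c("absolute", "signed")) {
  stopifnot(is(x, "CorrelationMatrix"))
  mode <- match.arg(mode)
  d <- switch(mode,
              absolute = 1 - abs(x@r),
              signed = (1 - x@r) / 2)
  diag(d) <- 0
  new("DistanceMatrix", d = d)
}

#' Write a labelled square matrix as CSV
#'
#' Optional writer for correlation and distance matrices.
#'
#' @param x a \linkS4class{CorrelationMatrix} or \linkS4class{DistanceMatrix}.
#' @param path output CSV file.
#' @return Invisibly, \code{path}.
#' @export
writeMatrixCSV <- function(x, path) {
  m <- if (is(x, "CorrelationMatrix")) corValues(x)
       else if (is(x, "DistanceMatrix")) distValues(x)
       else stop("x must be a CorrelationMatrix or DistanceMatrix")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("roi", colnames(m)), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = ","), con)
  invisible(path)
}
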