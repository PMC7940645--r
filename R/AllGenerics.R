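#' @import methods
NULL

#' Region-of-interest names
#'
#' @param x an object carrying ROI labels.
#' @return Character vector of ROI names.
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Diagnostic group label
#'
#' @param x an object carrying a group label.
#' @return Single character string.
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' Number of subjects
#'
#' @param x an object built from a subject cohort.
#' @return Integer count of subjects.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Subject-by-ROI uptake values
#'
#' @param x an \code{UptakeMatrix}.
#' @return Numeric matrix, subjects in rows, ROIs in columns.
#' @export
setGeneric("uptakeValues", function(x) standardGeneric("uptakeValues"))

#' Pearson correlation values
#'
#' @param x a \code{CorrelationMatrix}.
#' @return Symmetric numeric matrix of Pearson coefficients.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' Dissimilarity values
#'
#' @param x a \code{DistanceMatrix}.
#' @return Symmetric numeric matrix of ROI dissimilarities.
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' Betti-0 curve of a filtration
#'
#' @param x a \code{PersistenceResult}.
#' @return A \code{Betti0Curve}.
#' @export
setGeneric("bettiCurve", function(x) standardGeneric("bettiCurve"))

#' Evaluate the Betti-0 curve at filtration values
#'
#' Component count of the thresholded network (edge present iff
#' \eqn{d_{ij} \le \lambda}); right-continuous in \eqn{\lambda}.
#'
#' @param x a \code{Betti0Curve} or \code{PersistenceResult}.
#' @param lambda numeric vector of filtration values.
#' @return Integer vector of component counts.
#' @export
setGeneric("bettiAt", function(x, lambda) standardGeneric("bettiAt"))

#' Persistence barcode
#'
#' @param x a \code{PersistenceResult}.
#' @return data.frame with columns \code{birth} and \code{death}, one row per
#'   ROI component; all births are 0 and the last surviving component's death
#'   is recorded at the filtration ceiling.
#' @export
setGeneric("barcode", function(x) standardGeneric("barcode"))

#' Minimum spanning tree edges
#'
#' @param x a \code{PersistenceResult}.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
setGeneric("mstEdges", function(x) standardGeneric("mstEdges"))

#' Single-linkage ultrametric matrix
#'
#' @param x a \code{PersistenceResult}.
#' @return Symmetric matrix of minimax path distances (SLD).
#' @export
setGeneric("singleLinkageMatrix", function(x) standardGeneric("singleLinkageMatrix"))

#' Component merge events
#'
#' @param x a \code{PersistenceResult}.
#' @return data.frame of merge events ordered by filtration value.
#' @export
setGeneric("mergeTree", function(x) standardGeneric("mergeTree"))

#' SIP area under the curve
#'
#' Integral of the Betti-0 curve over the filtration range; equals
#' 1 + total MST weight. Larger values mean slower network integration.
#'
#' @param x a \code{Betti0Curve} or \code{PersistenceResult}.
#' @return Nonnegative scalar.
#' @export
setGeneric("sipAUC", function(x) standardGeneric("sipAUC"))

#' Convert to a base-R hclust dendrogram
#'
#' @param x a \code{PersistenceResult}.
#' @return An object of class \code{hclust} (single linkage).
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))

#' Graph node names
#'
#' @param x a \code{WeightedGraph}.
#' @return Character vector.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' Graph edge table
#'
#' @param x a \code{WeightedGraph}.
#' @return data.frame with columns \code{from}, \code{to}, \code{length}.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' Permutation p-value
#'
#' @param x a \code{PermutationResult}.
#' @return Scalar in (0, 1].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Permutation null draws
#'
#' @param x a \code{PermutationResult}.
#' @return Numeric vector of permuted differences.
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))

#' Observed group difference
#'
#' @param x a \code{PermutationResult}.
#' @return Scalar.
#' @export
setGeneric("observedDifference", function(x) standardGeneric("observedDifference"))
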