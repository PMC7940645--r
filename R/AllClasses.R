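#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata metadata<-
NULL

# ---------------------------------------------------------------- UptakeMatrix

#' Subject-by-ROI metabolic uptake matrix
#'
#' Container for one diagnostic group's regional metabolic values (e.g.
#' cerebellum-normalised FDG-PET SUVR). Internally a
#' \linkS4class{SummarizedExperiment} with ROIs as rows and subjects as
#' columns; the user-facing orientation (via \code{\link{uptakeValues}} and
#' the constructor) is subjects in rows, matching the on-disk table layout.
#'
#' @slot .Data inherited SummarizedExperiment slots; the single assay is
#'   named \code{"uptake"}.
#' @export
setClass("UptakeMatrix", contains = "SummarizedExperiment")

setValidity("UptakeMatrix", function(object) {
  if (!("uptake" %in% assayNames(object)))
    return("assay 'uptake' is missing")
  m <- assay(object, "uptake")
  if (!is.numeric(m))
    return("uptake values must be numeric")
  if (anyNA(m))
    return("uptake values contain missing entries; refusing to impute")
  if (ncol(m) < 3L)
    return(sprintf(
      "need at least 3 subjects for Pearson correlation, got %d (is the table transposed?)",
      ncol(m)))
  rn <- rownames(m)
  if (is.null(rn) || any(!nzchar(rn)))
    return("every ROI needs a non-empty name")
  if (anyDuplicated(rn))
    return(sprintf("duplicate ROI name(s): %s",
                   paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  lab <- metadata(object)$groupLabel
  if (!is.character(lab) || length(lab) != 1L)
    return("groupLabel must be a single character string")
  TRUE
})

#' Construct an UptakeMatrix
#'
#' @param values numeric matrix or data.frame, subjects in rows, ROIs in
#'   columns; column names are the ROI identifiers.
#' @param groupLabel character label of the diagnostic group.
#' @return An \linkS4class{UptakeMatrix}.
#' @examples
#' x <- UptakeMatrix(matrix(rnorm(15), 5, 3,
#'                          dimnames = list(NULL, c("a", "b", "c"))), "HC")
#' nSubjects(x)
#' @export
UptakeMatrix <- function(values, groupLabel = "group") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("the table needs a header row of ROI names")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("subj%03d", seq_len(nrow(values)))
  se <- SummarizedExperiment(assays = list(uptake = t(values)))
  metadata(se)$groupLabel <- as.character(groupLabel)
  new("UptakeMatrix", se)
}

#' @rdname uptakeValues
#' @export
setMethod("uptakeValues", "UptakeMatrix", function(x) t(assay(x, "uptake")))

#' @rdname roiNames
#' @export
setMethod("roiNames", "UptakeMatrix", function(x) rownames(x))

#' @rdname groupLabel
#' @export
setMethod("groupLabel", "UptakeMatrix", function(x) metadata(x)$groupLabel)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "UptakeMatrix", function(x) ncol(x))

setMethod("show", "UptakeMatrix", function(object) {
  cat(sprintf("UptakeMatrix '%s': %d subjects x %d ROIs\n",
              groupLabel(object), ncol(object), nrow(object)))
  cat("  ROIs:", paste(utils::head(rownames(object), 4), collapse = ", "),
      if (nrow(object) > 4) "..." else "", "\n")
})

# -------------------------------------------------------------------- Pathway

#' Neurotransmitter pathway definition
#'
#' An ordered set of ROIs forming one projection system (e.g. the
#' striatocortical dopaminergic network or the Ch4 lateral capsular
#' cholinergic network).
#'
#' @slot name pathway label.
#' @slot rois ordered character vector of ROI identifiers.
#' @slot laterality per-ROI tag: "left", "right", "bilateral" or "midline".
#' @export
setClass("Pathway",
         representation(name = "character",
                        rois = "character",
                        laterality = "character"))

setValidity("Pathway", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("pathway needs a single non-empty name")
  if (length(object@rois) == 0L)
    return(sprintf("pathway '%s' is empty", object@name))
  if (anyDuplicated(object@rois))
    return(sprintf("pathway '%s' lists duplicate ROI(s): %s", object@name,
                   paste(unique(object@rois[duplicated(object@rois)]),
                         collapse = ", ")))
  if (length(object@laterality) != length(object@rois))
    return("laterality must have one tag per ROI")
  ok <- object@laterality %in% c("left", "right", "bilateral", "midline")
  if (!all(ok))
    return(sprintf("unknown laterality tag(s): %s",
                   paste(unique(object@laterality[!ok]), collapse = ", ")))
  TRUE
})

#' Construct a Pathway
#'
#' @param name pathway label.
#' @param rois character vector of ROI identifiers, in dendrogram leaf order.
#' @param laterality per-ROI tags; recycled if length 1.
#' @return A \linkS4class{Pathway}.
#' @export
Pathway <- function(name, rois, laterality = "bilateral") {
  if (length(laterality) == 1L)
    laterality <- rep(laterality, length(rois))
  new("Pathway", name = name, rois = as.character(rois),
      laterality = as.character(laterality))
}

#' @rdname roiNames
#' @export
setMethod("roiNames", "Pathway", function(x) x@rois)

setMethod("show", "Pathway", function(object) {
  cat(sprintf("Pathway '%s' (%d ROIs)\n", object@name, length(object@rois)))
})

# ---------------------------------------------------- Correlation / Distance

#' Pearson correlation matrix of a pathway network
#'
#' @slot r symmetric matrix of Pearson coefficients, unit diagonal.
#' @slot nSubjects number of subjects the coefficients were estimated from.
#' @export
setClass("CorrelationMatrix",
         representation(r = "matrix", nSubjects = "integer"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    return("correlation matrix needs matching ROI dimnames")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12, check.attributes = FALSE)))
    return("correlation matrix must be symmetric")
  if (any(abs(diag(r) - 1) > 0)) return("diagonal must be exactly 1")
  if (any(r < -1 | r > 1)) return("entries must lie in [-1, 1]")
  if (object@nSubjects < 3L) return("nSubjects must be at least 3")
  TRUE
})

#' @rdname corValues
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@r)

#' @rdname roiNames
#' @export
setMethod("roiNames", "CorrelationMatrix", function(x) rownames(x@r))

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "CorrelationMatrix", function(x) x@nSubjects)

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d ROIs, %d subjects\n",
              nrow(object@r), object@nSubjects))
})

#' ROI dissimilarity matrix (the filtration substrate)
#'
#' Holds \eqn{d_{ij} = 1 - |r_{ij}|} (or the rescaled signed variant). Not
#' guaranteed to satisfy the triangle inequality; downstream code treats it
#' as a general dissimilarity, never as a metric.
#'
#' @slot d symmetric matrix in [0, 1] with zero diagonal.
#' @export
setClass("DistanceMatrix", representation(d = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("distance matrix needs matching ROI dimnames")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE)))
    return("distance matrix must be symmetric")
  if (any(diag(d) != 0)) return("diagonal must be exactly 0")
  if (any(d < 0 | d > 1)) return("entries must lie in [0, 1]")
  TRUE
})

#' Construct a DistanceMatrix from a raw dissimilarity matrix
#'
#' Mostly used internally and in tests; typical use goes through
#' \code{\link{toDistance}}.
#'
#' @param d symmetric numeric matrix in [0, 1], zero diagonal; ROI names are
#'   taken from dimnames or generated.
#' @return A \linkS4class{DistanceMatrix}.
#' @export
DistanceMatrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    nm <- sprintf("roi%02d", seq_len(nrow(d)))
    dimnames(d) <- list(nm, nm)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new("DistanceMatrix", d = d)
}

#' @rdname distValues
#' @export
setMethod("distValues", "DistanceMatrix", function(x) x@d)

#' @rdname roiNames
#' @export
setMethod("roiNames", "DistanceMatrix", function(x) rownames(x@d))

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d ROIs, off-diagonal range [%.3f, %.3f]\n",
              nrow(object@d),
              min(object@d[upper.tri(object@d)]),
              max(object@d[upper.tri(object@d)])))
})

# ------------------------------------------------------------- Betti0Curve

#' Betti-0 curve of a graph filtration
#'
#' Piecewise-constant, right-continuous count of connected components as the
#' filtration value sweeps [0, ceiling]. Breakpoints are the distinct MST
#' edge weights; the count starts at the number of ROIs and ends at 1.
#'
#' @slot breakpoints strictly increasing filtration values where the count drops.
#' @slot counts component count on each interval; length(breakpoints) + 1.
#' @slot ceiling upper integration limit (1 by default).
#' @export
setClass("Betti0Curve",
         representation(breakpoints = "numeric", counts = "integer",
                        ceiling = "numeric"))

setValidity("Betti0Curve", function(object) {
  b <- object@breakpoints
  k <- object@counts
  if (length(k) != length(b) + 1L)
    return("counts must have one more entry than breakpoints")
  if (length(b) && any(diff(b) <= 0))
    return("breakpoints must be strictly increasing")
  if (any(diff(k) >= 0))
    return("component counts must be strictly decreasing")
  if (length(object@ceiling) != 1L || object@ceiling <= 0)
    return("ceiling must be a positive scalar")
  if (length(b) && any(b > object@ceiling))
    return("breakpoints must not exceed the ceiling")
  TRUE
})

#' @rdname bettiAt
#' @export
setMethod("bettiAt", "Betti0Curve", function(x, lambda) {
  stopifnot(is.numeric(lambda), all(lambda >= 0))
  idx <- vapply(lambda, function(l) sum(x@breakpoints <= l), integer(1))
  x@counts[idx + 1L]
})

#' @rdname sipAUC
#' @export
setMethod("sipAUC", "Betti0Curve", function(x) {
  edges <- c(0, x@breakpoints, x@ceiling)
  sum(x@counts * diff(edges))
})

setMethod("show", "Betti0Curve", function(object) {
  cat(sprintf("Betti0Curve: %d -> 1 across %d breakpoints, AUC %.4f\n",
              object@counts[1], length(object@breakpoints), sipAUC(object)))
})

# -------------------------------------------------------- PersistenceResult

#' Zero-dimensional persistence summary of one pathway network
#'
#' Bundles every filtration-derived object for one DistanceMatrix: the exact
#' Betti-0 curve, the barcode, the minimum spanning tree, the single-linkage
#' ultrametric with its merge tree, and the SIP AUC statistic. The identity
#' sipAUC = 1 + total MST weight is checked at construction.
#'
#' @slot betti \linkS4class{Betti0Curve}.
#' @slot bars data.frame(birth, death), one bar per ROI.
#' @slot mst data.frame(from, to, weight) of the n - 1 tree edges.
#' @slot sld single-linkage ultrametric matrix.
#' @slot merges data.frame(lambda, a, b, step) of merge events.
#' @slot hmerge,hheight hclust-compatible merge matrix and heights.
#' @slot auc SIP AUC.
#' @export
setClass("PersistenceResult",
         representation(betti = "Betti0Curve", bars = "data.frame",
                        mst = "data.frame", sld = "matrix",
                        merges = "data.frame", hmerge = "matrix",
                        hheight = "numeric", auc = "numeric"))

setValidity("PersistenceResult", function(object) {
  n <- nrow(object@sld)
  if (nrow(object@bars) != n)
    return("barcode must have exactly one bar per ROI")
  if (nrow(object@mst) != n - 1L)
    return("MST must have n - 1 edges")
  finite_deaths <- sort(object@bars$death)[seq_len(n - 1L)]
  if (!isTRUE(all.equal(finite_deaths, sort(object@mst$weight),
                        tolerance = 1e-12)))
    return("barcode finite deaths must equal MST weights as a multiset")
  if (abs(object@auc - (object@betti@ceiling + sum(object@mst$weight))) > 1e-9)
    return("sipAUC must equal the filtration ceiling plus the total MST weight")
  TRUE
})

#' @rdname bettiCurve
#' @export
setMethod("bettiCurve", "PersistenceResult", function(x) x@betti)

#' @rdname bettiAt
#' @export
setMethod("bettiAt", "PersistenceResult",
          function(x, lambda) bettiAt(x@betti, lambda))

#' @rdname barcode
#' @export
setMethod("barcode", "PersistenceResult", function(x) x@bars)

#' @rdname mstEdges
#' @export
setMethod("mstEdges", "PersistenceResult", function(x) x@mst)

#' @rdname singleLinkageMatrix
#' @export
setMethod("singleLinkageMatrix", "PersistenceResult", function(x) x@sld)

#' @rdname mergeTree
#' @export
setMethod("mergeTree", "PersistenceResult", function(x) x@merges)

#' @rdname sipAUC
#' @export
setMethod("sipAUC", "PersistenceResult", function(x) x@auc)

#' @rdname roiNames
#' @export
setMethod("roiNames", "PersistenceResult", function(x) rownames(x@sld))

setMethod("show", "PersistenceResult", function(object) {
  cat(sprintf("PersistenceResult: %d ROIs, SIP AUC %.4f, MST total %.4f\n",
              nrow(object@sld), object@auc, sum(object@mst$weight)))
})

# ------------------------------------------------------------ WeightedGraph

#' Edge-filtered weighted network
#'
#' Undirected graph whose edge lengths are the retained ROI dissimilarities.
#'
#' @slot nodes ROI names.
#' @slot edges data.frame(from, to, length); each unordered pair at most once.
#' @slot retainRule record of the filtering applied.
#' @export
setClass("WeightedGraph",
         representation(nodes = "character", edges = "data.frame",
                        retainRule = "character"))

setValidity("WeightedGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "length") %in% names(e)))
    return("edges must have columns from, to, length")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$length <= 0)) return("edge lengths must be positive")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("each ROI pair may appear at most once")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
  }
  TRUE
})

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "WeightedGraph", function(x) x@nodes)

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "WeightedGraph", function(x) x@edges)

setMethod("show", "WeightedGraph", function(object) {
  cat(sprintf("WeightedGraph: %d nodes, %d edges (%s)\n",
              length(object@nodes), nrow(object@edges), object@retainRule))
})

# -------------------------------------------------------- PermutationResult

#' Result of a two-group permutation test on a network statistic
#'
#' @slot metricName registered statistic name.
#' @slot groupPair the two group labels compared.
#' @slot observedDifference observed statistic difference (group1 - group2).
#' @slot nullDraws permuted differences.
#' @slot pValue two-sided add-one p-value in (0, 1].
#' @slot nPermutations number of label permutations.
#' @slot seed RNG seed used.
#' @export
setClass("PermutationResult",
         representation(metricName = "character", groupPair = "character",
                        observedDifference = "numeric", nullDraws = "numeric",
                        pValue = "numeric", nPermutations = "integer",
                        seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullDraws) != object@nPermutations)
    return("nullDraws must have one entry per permutation")
  expected <- (1 + sum(abs(object@nullDraws) >=
                         abs(object@observedDifference))) /
    (1 + object@nPermutations)
  if (abs(object@pValue - expected) > 1e-12)
    return("pValue must follow the add-one permutation formula")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' @rdname pValue
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname nullDraws
#' @export
setMethod("nullDraws", "PermutationResult", function(x) x@nullDraws)

#' @rdname observedDifference
#' @export
setMethod("observedDifference", "PermutationResult",
          function(x) x@observedDifference)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult [%s] %s vs %s: diff %.4g, p = %.4g (%d permutations)\n",
    object@metricName, object@groupPair[1], object@groupPair[2],
    object@observedDifference, object@pValue, object@nPermutations))
})

# ------------------------------------------------------------ SyntheticSpec

#' Specification of a synthetic multi-group cohort
#'
#' Describes a block-exchangeable covariance world: ROIs are partitioned into
#' pathway blocks; latent values correlate at \code{within[g]} inside a block
#' and \code{between} across blocks, and independent Gaussian measurement
#' noise of sd \code{noiseSd} is added, which attenuates observable
#' correlations by 1 / (1 + noiseSd^2).
#'
#' @slot groupNames group labels.
#' @slot groupSizes subjects per group (each >= 3).
#' @slot layout named list: block name -> character vector of ROI names.
#' @slot within per-group within-block latent correlation, in [0, 1).
#' @slot between cross-block latent correlation, in [0, 1), <= min(within).
#' @slot noiseSd standard deviation of additive measurement noise.
#' @slot seed master RNG seed; per-group streams are derived from it.
#' @export
setClass("SyntheticSpec",
         representation(groupNames = "character", groupSizes = "integer",
                        layout = "list", within = "numeric",
                        between = "numeric", noiseSd = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  g <- length(object@groupNames)
  if (g == 0L) return("at least one group is required")
  if (length(object@groupSizes) != g || length(object@within) != g)
    return("groupSizes and within must have one entry per group")
  if (any(object@groupSizes < 3L))
    return("every group size must be at least 3 (Pearson correlation needs >= 3 observations)")
  if (any(object@within < 0 | object@within >= 1))
    return("within-block strengths must lie in [0, 1)")
  if (object@between < 0 || object@between >= 1)
    return("between-block strength must lie in [0, 1)")
  if (object@between > min(object@within))
    return(sprintf("between-block strength (%.3f) must not exceed the smallest within-block strength (%.3f)",
                   object@between, min(object@within)))
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  rois <- unlist(object@layout, use.names = FALSE)
  if (!length(rois)) return("layout must define at least one ROI")
  if (anyDuplicated(rois))
    return("layout blocks must not share ROI names")
  TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d groups (%s), %d ROIs in %d blocks, noiseSd %.2f, seed %d\n",
    length(object@groupNames),
    paste(sprintf("%s n=%d w=%.2f", object@groupNames, object@groupSizes,
                  object@within), collapse = "; "),
    length(unlist(object@layout)), length(object@layout),
    object@noiseSd, object@seed))
})

#' @rdname roiNames
#' @export
setMethod("roiNames", "SyntheticSpec",
          function(x) unlist(x@layout, use.names = FALSE))
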