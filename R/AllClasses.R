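#' EmbeddingSet: a pool of item embeddings
#'
#' Holds one real-valued feature vector per item, with unique item
#' identifiers as row names. Rows are items (N), columns are embedding
#' dimensions (d). All values must be finite.
#'
#' @slot values numeric matrix, N x d, rownames are the unique item ids.
#' @export
setClass("EmbeddingSet", representation(values = "matrix"))

setValidity("EmbeddingSet", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("embedding values must be numeric")
  if (nrow(v) < 1L) return("need at least one item (N >= 1)")
  if (ncol(v) < 1L) return("need at least one embedding dimension (d >= 1)")
  if (is.null(rownames(v))) return("item ids (rownames) are required")
  if (anyDuplicated(rownames(v)))
    return(sprintf("duplicate item id: '%s'",
                   rownames(v)[anyDuplicated(rownames(v))]))
  if (!all(is.finite(v))) return("all embedding values must be finite")
  TRUE
})

#' KMeansModel: a fitted K-means clustering
#'
#' Result of [kmeansFit()]. At convergence each non-empty cluster's centroid
#' is the mean of its members, every item is assigned to its nearest centroid
#' (squared Euclidean, ties to the lowest cluster index), and `inertia` is
#' the sum of squared distances of items to their assigned centroids.
#'
#' @slot centroids numeric matrix, k x d.
#' @slot assignments integer vector of cluster indices in 1..k, one per item.
#' @slot inertia non-negative scalar, the K-means objective.
#' @slot nIter iterations run by the winning restart.
#' @slot clusterSizes integer vector of k member counts (all positive after
#'   empty-cluster repair).
#' @slot trace inertia recorded at each Lloyd assignment step (non-increasing).
#' @slot converged logical, whether assignments reached a fixed point.
#' @slot control list echoing the fit configuration.
#' @export
setClass("KMeansModel", representation(
  centroids = "matrix", assignments = "integer", inertia = "numeric",
  nIter = "integer", clusterSizes = "integer", trace = "numeric",
  converged = "logical", control = "list"))

setValidity("KMeansModel", function(object) {
  k <- nrow(object@centroids)
  if (k < 1L) return("need at least one centroid")
  if (length(object@clusterSizes) != k)
    return("clusterSizes length must equal the number of centroids")
  if (any(object@assignments < 1L) || any(object@assignments > k))
    return("assignments must lie in 1..k")
  if (sum(object@clusterSizes) != length(object@assignments))
    return("cluster sizes must sum to the number of items")
  if (object@inertia < 0) return("inertia must be non-negative")
  TRUE
})

#' SelectionPlan: how to build a coreset
#'
#' Exactly one of `m` (target coreset size) or `fraction` (retention
#' fraction of the pool) must be set; class-based strategies additionally
#' require `nClasses`, the assumed number of classes in the pool.
#'
#' @slot strategy one of `"images"` (K = M, one item per cluster),
#'   `"classes"` (K = number of classes), `"2classes"` (K = twice the number
#'   of classes) or `"random"` (uniform baseline, no clustering).
#' @slot m target coreset size M (NA when `fraction` is used).
#' @slot fraction retention fraction in (0, 1] (NA when `m` is used).
#' @slot nClasses assumed class count (required for class-based strategies).
#' @slot seed integer seed governing clustering and sampling.
#' @export
setClass("SelectionPlan", representation(
  strategy = "character", m = "integer", fraction = "numeric",
  nClasses = "integer", seed = "integer"))

setValidity("SelectionPlan", function(object) {
  ok <- c("images", "classes", "2classes", "random")
  if (length(object@strategy) != 1L || !object@strategy %in% ok)
    return(sprintf("strategy must be one of %s", paste(ok, collapse = ", ")))
  hasM <- !is.na(object@m)
  hasF <- !is.na(object@fraction)
  if (hasM == hasF)
    return("exactly one of m / fraction must be provided")
  if (hasM && object@m < 1L) return("coreset size M must be positive")
  if (hasF && (object@fraction <= 0 || object@fraction > 1))
    return("retention fraction must lie in (0, 1]")
  if (object@strategy %in% c("classes", "2classes") && is.na(object@nClasses))
    return("class-based strategies require nClasses")
  if (!is.na(object@nClasses) && object@nClasses < 1L)
    return("nClasses must be positive")
  TRUE
})

#' CoresetResult: the selected items
#'
#' @slot selectedIds the M distinct selected item ids.
#' @slot provenance integer cluster index each id was drawn from (NA for the
#'   random baseline).
#' @slot kUsed number of clusters fitted (NA for the random baseline).
#' @slot plan the [SelectionPlan-class] that produced the result.
#' @export
setClass("CoresetResult", representation(
  selectedIds = "character", provenance = "integer", kUsed = "integer",
  plan = "SelectionPlan"))

setValidity("CoresetResult", function(object) {
  if (anyDuplicated(object@selectedIds))
    return("selected ids must be distinct")
  if (length(object@provenance) != length(object@selectedIds))
    return("provenance must align with selectedIds")
  TRUE
})

#' EvalReport: coverage and validity summary for a coreset
#'
#' @slot macroF1 macro-averaged F1 in `[0, 1]` (NA when no classifier run).
#' @slot perClassF1 named per-class F1 (empty when no classifier run).
#' @slot classesEmpty number of ground-truth classes with no selected item.
#' @slot perClassSelectedCounts named per-class selected counts (sums to M).
#' @slot daviesBouldin Davies-Bouldin index of the true classes in embedding
#'   space (NA when not computed; 0 is best).
#' @slot silhouette mean silhouette of the true classes (NA when not
#'   computed; in `[-1, 1]`, 1 is best).
#' @export
setClass("EvalReport", representation(
  macroF1 = "numeric", perClassF1 = "numeric", classesEmpty = "integer",
  perClassSelectedCounts = "numeric", daviesBouldin = "numeric",
  silhouette = "numeric"))
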