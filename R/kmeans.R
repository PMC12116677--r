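#' Fit K-means to an embedding pool
#'
#' From-scratch seeded K-means: k-means++ (or random-point) initialization,
#' Lloyd iteration, `nInit` restarts keeping the best model by inertia, and
#' deterministic empty-cluster repair (an empty cluster is reseeded at the
#' point farthest from its assigned centroid, so every returned cluster is
#' non-empty). Distances are squared Euclidean on the raw embeddings.
#'
#' A run stops when the assignment reaches a fixed point, when the relative
#' inertia improvement between consecutive iterations drops below `tol`, or
#' at `maxIter`. Returned centroids are always the exact means of the final
#' assignment and the reported inertia is computed against them.
#'
#' All randomness flows through R's RNG, so the fit is bit-reproducible
#' given `seed`.
#'
#' @param x an [EmbeddingSet-class] or numeric matrix with row ids
#' @param k number of clusters (1 <= k <= N)
#' @param maxIter Lloyd iteration cap per restart
#' @param tol relative inertia-improvement stopping threshold
#' @param nInit number of restarts; the best model by inertia is kept
#' @param seed integer seed
#' @param init `"kmeanspp"` (default) or `"random_points"`
#' @param initCenters optional explicit k x d initial centroids; when given,
#'   a single run is performed from them and `init`/`nInit` are ignored
#' @return a [KMeansModel-class]
#' @examples
#' e <- EmbeddingSet(rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1)),
#'                   ids = paste0("p", 1:4))
#' m <- kmeansFit(e, k = 2, seed = 1)
#' inertia(m)  # 1.0: the optimal 2-partition
#' @export
kmeansFit <- function(x, k, maxIter = 300L, tol = 1e-4, nInit = 10L,
                      seed = 1L, init = c("kmeanspp", "random_points"),
                      initCenters = NULL) {
  v <- if (is(x, "EmbeddingSet")) embMatrix(x) else as.matrix(x)
  storage.mode(v) <- "double"
  if (!all(is.finite(v))) stop("embeddings must be finite")
  n <- nrow(v)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the number of items N = %d", k, n))
  init <- match.arg(init)
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1")
  if (tol < 0) stop("tol must be >= 0")
  nInit <- as.integer(nInit)
  if (nInit < 1L) stop("nInit must be >= 1")

  set.seed(as.integer(seed))
  best <- NULL
  if (!is.null(initCenters)) {
    ic <- as.matrix(initCenters)
    storage.mode(ic) <- "double"
    if (ncol(ic) != ncol(v)) stop("initCenters dimension mismatch")
    if (nrow(ic) != k) stop("initCenters must have k rows")
    best <- cpp_lloyd(v, ic, maxIter, tol)
  } else {
    for (r in seq_len(nInit)) {
      centers <- if (init == "kmeanspp") cpp_kmeanspp(v, k)
                 else v[sample.int(n, k), , drop = FALSE]
      run <- cpp_lloyd(v, centers, maxIter, tol)
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  }
  new("KMeansModel",
      centroids = best$centroids,
      assignments = as.integer(best$assignments),
      inertia = as.numeric(best$inertia),
      nIter = as.integer(best$iters),
      clusterSizes = as.integer(best$sizes),
      trace = as.numeric(best$trace),
      converged = isTRUE(best$converged),
      control = list(k = k, maxIter = maxIter, tol = tol, nInit = nInit,
                     seed = as.integer(seed), init = init))
}

#' @rdname coresel-accessors
#' @export
setMethod("centroids", "KMeansModel", function(object) object@centroids)

#' @rdname coresel-accessors
#' @export
setMethod("clusterAssignments", "KMeansModel",
          function(object) object@assignments)

#' @rdname coresel-accessors
#' @export
setMethod("clusterSizes", "KMeansModel", function(object) object@clusterSizes)

#' @rdname coresel-accessors
#' @export
setMethod("nClusters", "KMeansModel",
          function(object) nrow(object@centroids))

#' @rdname coresel-accessors
#' @export
setMethod("inertia", "KMeansModel", function(object) object@inertia)

#' @export
setMethod("show", "KMeansModel", function(object) {
  cat(sprintf(
    "KMeansModel: k = %d over %d items, inertia = %.6g (%d iterations%s)\n",
    nClusters(object), length(object@assignments), inertia(object),
    object@nIter, if (object@converged) ", converged" else ""))
})

#' Assign items to the nearest centroid of a fitted model
#'
#' Ties are broken toward the lowest cluster index.
#'
#' @param model a [KMeansModel-class]
#' @param x an [EmbeddingSet-class] or matrix with the model's
#'   dimensionality
#' @return integer vector of cluster indices in 1..k
#' @export
assignToClusters <- function(model, x) {
  stopifnot(is(model, "KMeansModel"))
  v <- if (is(x, "EmbeddingSet")) embMatrix(x) else as.matrix(x)
  storage.mode(v) <- "double"
  if (ncol(v) != ncol(centroids(model)))
    stop(sprintf("dimension mismatch: items have d = %d, model has d = %d",
                 ncol(v), ncol(centroids(model))))
  as.integer(cpp_assign(v, centroids(model)))
}

#' K-means objective for an explicit clustering
#'
#' Sum of squared Euclidean distances of items to their assigned centroids.
#'
#' @param x an [EmbeddingSet-class] or matrix
#' @param centers k x d centroid matrix
#' @param assignments integer cluster index per item, in 1..k
#' @return non-negative scalar
#' @export
clusterInertia <- function(x, centers, assignments) {
  v <- if (is(x, "EmbeddingSet")) embMatrix(x) else as.matrix(x)
  centers <- as.matrix(centers)
  if (ncol(v) != ncol(centers)) stop("dimension mismatch")
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(v)) stop("one assignment per item required")
  if (any(assignments < 1L) || any(assignments > nrow(centers)))
    stop("assignment index out of range 1..k")
  sum((v - centers[assignments, , drop = FALSE])^2)
}
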