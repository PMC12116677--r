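#' Subset size for a retention fraction
#'
#' Converts a retention fraction of the pool into an integer coreset size.
#' The `"floor"` convention truncates `poolN * fraction` (the default;
#' e.g. 0.3% of a 48,875-item pool gives 146); `"nearest"` rounds half away
#' from zero. A tiny epsilon guards against floating-point representation of
#' the product.
#'
#' @param poolN pool size (>= 1)
#' @param fraction retention fraction in (0, 1]
#' @param convention `"floor"` or `"nearest"`
#' @return integer in 1..poolN
#' @examples
#' subsetSize(48875, 0.003)             # 146
#' subsetSize(6633, 0.3, "nearest")     # 1990
#' @export
subsetSize <- function(poolN, fraction, convention = c("floor", "nearest")) {
  convention <- match.arg(convention)
  poolN <- as.integer(poolN)
  if (is.na(poolN) || poolN < 1L) stop("poolN must be >= 1")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  p <- poolN * fraction
  m <- if (convention == "floor") floor(p + 1e-9) else floor(p + 0.5)
  m <- as.integer(m)
  if (m < 1L)
    stop(sprintf("fraction %g too small for a pool of %d items",
                 fraction, poolN))
  min(m, poolN)
}

#' Per-cluster sampling quotas
#'
#' Splits a coreset budget of `M` items across `K` clusters as evenly as
#' possible: base quota `floor(M/K)` everywhere, one extra to the
#' `M %% K` largest clusters (ties by cluster index). Quotas are capped at
#' the cluster size; any resulting deficit is redistributed greedily, one
#' item at a time, to the cluster with the largest remaining capacity.
#' When every cluster is large enough the quotas differ by at most 1.
#'
#' @param M coreset size
#' @param sizes integer vector of K cluster sizes, summing to >= M
#' @return integer vector of K quotas summing to M, each <= its cluster size
#' @examples
#' allocatePerCluster(146, rep(100, 38))   # 3s and 4s: 38*3 + 32 = 146
#' allocatePerCluster(6, c(1, 1, 100))     # 1 1 4
#' @export
allocatePerCluster <- function(M, sizes) {
  M <- as.integer(M)
  sizes <- as.integer(sizes)
  if (M < 1L) stop("M must be >= 1")
  if (any(sizes < 0L)) stop("cluster sizes must be non-negative")
  if (sum(sizes) < M)
    stop(sprintf("pool too small: clusters hold %d items, M = %d",
                 sum(sizes), M))
  K <- length(sizes)
  alloc <- rep(M %/% K, K)
  extra <- M %% K
  if (extra > 0L) {
    ord <- order(sizes, decreasing = TRUE)  # stable: ties by cluster index
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
  }
  alloc <- pmin(alloc, sizes)
  deficit <- M - sum(alloc)
  while (deficit > 0L) {
    capacity <- sizes - alloc
    i <- which.max(capacity)   # first max: ties by cluster index
    alloc[i] <- alloc[i] + 1L
    deficit <- deficit - 1L
  }
  alloc
}

#' Build a selection plan
#'
#' @param strategy `"images"` (K = M, the strongest configuration:
#'   one cluster per coreset slot), `"classes"` (K = class count),
#'   `"2classes"` (K = twice the class count) or `"random"` (baseline)
#' @param m target coreset size M; mutually exclusive with `fraction`
#' @param fraction retention fraction in (0, 1]
#' @param nClasses assumed class count (required for the class strategies)
#' @param seed integer seed
#' @return a [SelectionPlan-class]
#' @export
selectionPlan <- function(strategy, m = NA, fraction = NA, nClasses = NA,
                          seed = 1L) {
  new("SelectionPlan", strategy = as.character(strategy),
      m = as.integer(m), fraction = as.numeric(fraction),
      nClasses = as.integer(nClasses), seed = as.integer(seed))
}

#' @export
setMethod("show", "SelectionPlan", function(object) {
  tgt <- if (!is.na(object@m)) sprintf("M = %d", object@m)
         else sprintf("fraction = %g", object@fraction)
  cat(sprintf("SelectionPlan: strategy = %s, %s, seed = %d\n",
              object@strategy, tgt, object@seed))
})

#' @rdname coresel-accessors
#' @export
setMethod("selectedIds", "CoresetResult", function(object) object@selectedIds)

#' @rdname coresel-accessors
#' @export
setMethod("provenance", "CoresetResult", function(object) object@provenance)

#' @rdname coresel-accessors
#' @export
setMethod("nItems", "CoresetResult",
          function(x) length(x@selectedIds))

#' @export
setMethod("show", "CoresetResult", function(object) {
  cat(sprintf("CoresetResult: %d items (strategy %s, k = %s)\n",
              length(object@selectedIds), object@plan@strategy,
              ifelse(is.na(object@kUsed), "-", object@kUsed)))
})

.resolveM <- function(plan, n, convention = "floor") {
  if (!is.na(plan@m)) {
    if (plan@m > n)
      stop(sprintf("M = %d exceeds the pool size N = %d", plan@m, n))
    as.integer(plan@m)
  } else {
    subsetSize(n, plan@fraction, convention)
  }
}

#' Select a coreset from an embedding pool
#'
#' Implements the cluster-then-sample coreset selection. For strategy
#' `"images"` K-means is fitted with K = M and one item is drawn uniformly
#' from each cluster; for `"classes"` / `"2classes"` K equals the (doubled)
#' assumed class count and per-cluster quotas come from
#' [allocatePerCluster()], so every cluster contributes approximately M/K
#' items; `"random"` draws M ids uniformly without replacement, ignoring
#' the clustering entirely. Deterministic given the plan seed: the
#' clustering and the within-cluster draws use seeds derived from it.
#'
#' @param x an [EmbeddingSet-class]
#' @param plan a [SelectionPlan-class]
#' @param within within-cluster sampling: `"uniform"` (default) or
#'   `"nearest"` (the quota items nearest the centroid)
#' @param convention fraction-to-size convention, see [subsetSize()]
#' @param kmeansControl list of overrides passed to [kmeansFit()]
#'   (`maxIter`, `tol`, `nInit`, `init`)
#' @return a [CoresetResult-class]
#' @export
selectCoreset <- function(x, plan, within = c("uniform", "nearest"),
                          convention = "floor", kmeansControl = list()) {
  stopifnot(is(x, "EmbeddingSet"), is(plan, "SelectionPlan"))
  validObject(plan)
  within <- match.arg(within)
  n <- nItems(x)
  M <- .resolveM(plan, n, convention)

  if (plan@strategy == "random")
    return(randomSelect(itemIds(x), M, plan@seed, plan = plan))

  k <- switch(plan@strategy,
              images = M,
              classes = plan@nClasses,
              `2classes` = 2L * plan@nClasses)
  if (k > n)
    stop(sprintf("k = %d exceeds the pool size N = %d", k, n))
  if (k > M)
    stop(sprintf("k = %d exceeds the coreset size M = %d; %s",
                 k, M, "use fewer clusters or a larger budget"))

  ctrl <- modifyList(list(maxIter = 300L, tol = 1e-4, nInit = 10L,
                          init = "kmeanspp"), kmeansControl)
  km <- kmeansFit(x, k, maxIter = ctrl$maxIter, tol = ctrl$tol,
                  nInit = ctrl$nInit, init = ctrl$init,
                  seed = deriveSeed(plan@seed, "kmeans"))
  alloc <- if (plan@strategy == "images") rep(1L, k)
           else allocatePerCluster(M, clusterSizes(km))

  set.seed(deriveSeed(plan@seed, "within-cluster-sample"))
  ids <- itemIds(x)
  asg <- clusterAssignments(km)
  sel <- character(0); prov <- integer(0)
  for (j in seq_len(k)) {
    if (alloc[j] == 0L) next
    members <- which(asg == j)
    pick <- if (within == "uniform") {
      members[sample.int(length(members), alloc[j])]
    } else {
      d2 <- rowSums((embMatrix(x)[members, , drop = FALSE] -
                     matrix(centroids(km)[j, ], length(members),
                            embDim(x), byrow = TRUE))^2)
      members[order(d2)][seq_len(alloc[j])]
    }
    sel <- c(sel, ids[pick])
    prov <- c(prov, rep(j, alloc[j]))
  }
  new("CoresetResult", selectedIds = sel, provenance = prov,
      kUsed = as.integer(k), plan = plan)
}

#' Random-baseline selection
#'
#' Uniform draw of M ids without replacement; the baseline the clustered
#' strategies are benchmarked against.
#'
#' @param ids pool item ids
#' @param m coreset size (1 <= m <= length(ids))
#' @param seed integer seed
#' @param plan optional [SelectionPlan-class] to echo in the result
#' @return a [CoresetResult-class] with NA provenance
#' @export
randomSelect <- function(ids, m, seed = 1L, plan = NULL) {
  ids <- as.character(ids)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("coreset size M must be positive")
  if (m > length(ids))
    stop(sprintf("M = %d exceeds the pool size N = %d", m, length(ids)))
  if (anyDuplicated(ids)) stop("pool ids must be unique")
  if (is.null(plan))
    plan <- selectionPlan("random", m = m, seed = seed)
  set.seed(deriveSeed(as.integer(seed), "random-baseline"))
  sel <- ids[sample.int(length(ids), m)]
  new("CoresetResult", selectedIds = sel,
      provenance = rep(NA_integer_, m), kUsed = NA_integer_, plan = plan)
}
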