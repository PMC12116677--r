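#' Per-class and macro-averaged F1
#'
#' `f1Scores()` computes, for every class in `classSet`, precision, recall
#' and their harmonic mean from the confusion counts; a class with zero
#' precision + recall (or absent from both truth and predictions)
#' contributes an F1 of 0 and is flagged as degenerate. `macroF1()` is the
#' unweighted mean over `classSet` — insensitive to class frequency, which
#' is what matters under heavy imbalance.
#'
#' @param yTrue true class labels
#' @param yPred predicted class labels
#' @param classSet classes to average over; defaults to the classes present
#'   in `yTrue`
#' @return `f1Scores()`: list with `perClass` (named numeric), `macro`
#'   (scalar) and `degenerate` (character vector of flagged classes).
#'   `macroF1()`: the macro scalar.
#' @examples
#' macroF1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 0.7333...
#' @export
f1Scores <- function(yTrue, yPred, classSet = NULL) {
  if (length(yTrue) == 0L) stop("empty inputs")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (is.null(classSet)) classSet <- sort(unique(yTrue))
  classSet <- as.character(classSet)
  if (!all(yTrue %in% classSet))
    stop("true labels outside the class set")
  perClass <- numeric(length(classSet))
  names(perClass) <- classSet
  degenerate <- character(0)
  for (cl in classSet) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    if (tp + fp + fn == 0L) {
      perClass[cl] <- 0
      degenerate <- c(degenerate, cl)
    } else if (tp == 0L) {
      perClass[cl] <- 0
    } else {
      prec <- tp / (tp + fp)
      rec <- tp / (tp + fn)
      perClass[cl] <- 2 * prec * rec / (prec + rec)
    }
  }
  list(perClass = perClass, macro = mean(perClass), degenerate = degenerate)
}

#' @rdname f1Scores
#' @export
macroF1 <- function(yTrue, yPred, classSet = NULL) {
  f1Scores(yTrue, yPred, classSet)$macro
}

.groupStats <- function(v, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  cent <- t(vapply(groups, function(g)
    colMeans(v[labels == g, , drop = FALSE]), numeric(ncol(v))))
  list(groups = groups, centroids = cent)
}

#' Davies-Bouldin index
#'
#' Average, over groups, of the worst similarity ratio
#' `(S_i + S_j) / d(c_i, c_j)` with `S` the mean Euclidean distance of
#' members to their group centroid and `d(c_i, c_j)` the centroid distance.
#' Lower is better; 0 is the ideal of infinitely tight, well-separated
#' groups. Computed on the true class labels it measures how well a feature
#' extractor separates classes in embedding space.
#'
#' @param x an [EmbeddingSet-class] or numeric matrix
#' @param labels group label per item (>= 2 non-empty groups)
#' @return non-negative scalar
#' @examples
#' v <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' daviesBouldin(v, c(1, 1, 2, 2))  # 0.1
#' @export
daviesBouldin <- function(x, labels) {
  v <- if (is(x, "EmbeddingSet")) embMatrix(x) else as.matrix(x)
  if (length(labels) != nrow(v)) stop("one label per item required")
  gs <- .groupStats(v, labels)
  g <- length(gs$groups)
  s <- vapply(seq_len(g), function(i) {
    member <- v[as.character(labels) == gs$groups[i], , drop = FALSE]
    mean(sqrt(rowSums((member - matrix(gs$centroids[i, ], nrow(member),
                                       ncol(v), byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(gs$centroids))
  r <- vapply(seq_len(g), function(i) {
    ratio <- (s[i] + s[-i]) / cd[i, -i]
    max(ratio)
  }, numeric(1))
  mean(r)
}

#' Mean silhouette score
#'
#' Per item, `s = (b - a) / max(a, b)` with `a` the mean Euclidean distance
#' to co-members of its own group and `b` the smallest mean distance to any
#' other group; items whose group has no other member score 0. The mean
#' over items lies in `[-1, 1]`; values near 1 indicate compact,
#' well-separated groups.
#'
#' @inheritParams daviesBouldin
#' @return scalar in `[-1, 1]`
#' @export
silhouetteScore <- function(x, labels) {
  v <- if (is(x, "EmbeddingSet")) embMatrix(x) else as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(v)) stop("one label per item required")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  D <- as.matrix(stats::dist(v))
  G <- vapply(groups, function(g) as.numeric(labels == g),
              numeric(nrow(v)))                      # n x g indicator
  sums <- D %*% G                                    # dist sums per group
  counts <- colSums(G)
  gi <- match(labels, groups)
  n <- nrow(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- counts[gi[i]] - 1
    if (own == 0) { s[i] <- 0; next }
    a <- sums[i, gi[i]] / own
    b <- min(sums[i, -gi[i]] / counts[-gi[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Class coverage of a coreset
#'
#' Counts how many selected items each ground-truth class received and how
#' many classes received none. Under random reduction of a heavily
#' imbalanced pool, rare classes are often left with zero selected images
#' (and hence F1 = 0 downstream); cluster-based selection on well-separated
#' embeddings covers every class.
#'
#' @param result a [CoresetResult-class]
#' @param manifest a labeled manifest covering all selected ids
#' @return list with `classesEmpty` (integer) and `perClassCounts` (named
#'   integer over the manifest's full class set, summing to M)
#' @export
classCoverage <- function(result, manifest) {
  stopifnot(is(result, "CoresetResult"))
  validateManifest(manifest)
  if (!"label" %in% names(manifest))
    stop("manifest has no labels; coverage needs ground truth")
  sel <- selectedIds(result)
  idx <- match(sel, manifest$id)
  if (anyNA(idx))
    stop("missing label for selected id(s): ",
         paste(head(sel[is.na(idx)], 3), collapse = ", "))
  classes <- sort(unique(manifest$label))
  counts <- table(factor(manifest$label[idx], levels = classes))
  counts <- stats::setNames(as.integer(counts), classes)
  list(classesEmpty = sum(counts == 0L), perClassCounts = counts)
}

#' Assemble an evaluation report for a coreset
#'
#' Combines class coverage with the two cluster-validity indices computed
#' on the full pool under its true class labels (how separable the classes
#' are in embedding space). The classifier-based macro-F1 is filled by
#' [runBenchmark()]; here it is NA unless predictions are supplied.
#'
#' @param x the pool [EmbeddingSet-class]
#' @param manifest labeled manifest for the pool
#' @param result a [CoresetResult-class]
#' @param validityIndices compute Davies-Bouldin and silhouette (quadratic
#'   in N for the silhouette; disable for very large pools)
#' @return an [EvalReport-class]
#' @export
evaluateSelection <- function(x, manifest, result, validityIndices = TRUE) {
  cov <- classCoverage(result, manifest)
  db <- sil <- NA_real_
  if (validityIndices) {
    lab <- manifest$label[match(itemIds(x), manifest$id)]
    if (anyNA(lab)) stop("manifest must label every pool item")
    db <- daviesBouldin(x, lab)
    sil <- silhouetteScore(x, lab)
  }
  new("EvalReport", macroF1 = NA_real_, perClassF1 = numeric(0),
      classesEmpty = as.integer(cov$classesEmpty),
      perClassSelectedCounts = as.numeric(cov$perClassCounts) |>
        stats::setNames(names(cov$perClassCounts)),
      daviesBouldin = db, silhouette = sil)
}

#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (!is.na(object@macroF1))
    cat(sprintf("  macro-F1: %.4f over %d classes\n", object@macroF1,
                length(object@perClassF1)))
  cat(sprintf("  classes with no selected item: %d of %d\n",
              object@classesEmpty, length(object@perClassSelectedCounts)))
  if (!is.na(object@daviesBouldin))
    cat(sprintf("  Davies-Bouldin: %.4f   silhouette: %.4f\n",
                object@daviesBouldin, object@silhouette))
})
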