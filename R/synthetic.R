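#' Specify a synthetic embedding cloud
#'
#' Describes an imbalanced multi-class Gaussian-mixture embedding pool: each
#' class is one (or several, via `submodesPerClass`) isotropic Gaussian mode
#' in `dim` dimensions. Class centers are drawn uniformly on a hypersphere
#' of radius `separation * noiseSd`, so a single knob controls how well the
#' classes separate relative to their within-class spread; sub-mode centers
#' are offset from the class center by half that radius to mimic intra-class
#' variability.
#'
#' Class counts are given explicitly (`classCounts`) or as a power-law
#' profile: `count_c` proportional to `rank^-imbalanceExponent`, rescaled to
#' `totalN` and floored at 1.
#'
#' @param nClasses number of classes
#' @param classCounts integer vector of per-class item counts (all >= 1);
#'   mutually exclusive with `imbalanceExponent`
#' @param imbalanceExponent power-law exponent (>= 0) for the count profile
#' @param totalN total item count when using `imbalanceExponent`
#' @param dim embedding dimensionality
#' @param separation ratio of inter-class centroid spacing to within-class
#'   spread (> 0)
#' @param submodesPerClass Gaussian sub-modes per class (default 1)
#' @param noiseSd within-mode standard deviation per dimension (> 0)
#' @param seed integer seed
#' @return a `BlobSpec` (validated list)
#' @seealso [generateBlobs()], [powerLawCounts()]
#' @export
blobSpec <- function(nClasses, classCounts = NULL, imbalanceExponent = NULL,
                     totalN = NULL, dim, separation, submodesPerClass = 1L,
                     noiseSd = 1, seed = 1L) {
  nClasses <- as.integer(nClasses)
  if (length(nClasses) != 1L || is.na(nClasses) || nClasses < 1L)
    stop("nClasses must be a positive integer")
  if (is.null(classCounts)) {
    if (is.null(imbalanceExponent) || is.null(totalN))
      stop("provide classCounts, or imbalanceExponent with totalN")
    classCounts <- powerLawCounts(nClasses, imbalanceExponent, totalN)
  } else {
    if (!is.null(imbalanceExponent))
      stop("classCounts and imbalanceExponent are mutually exclusive")
    classCounts <- as.integer(classCounts)
    if (length(classCounts) != nClasses)
      stop("classCounts must have length nClasses")
    if (anyNA(classCounts) || any(classCounts < 1L))
      stop("all class counts must be >= 1")
  }
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("dim must be >= 1")
  if (!is.numeric(separation) || separation <= 0)
    stop("separation must be > 0")
  submodesPerClass <- as.integer(submodesPerClass)
  if (is.na(submodesPerClass) || submodesPerClass < 1L)
    stop("submodesPerClass must be >= 1")
  if (!is.numeric(noiseSd) || noiseSd <= 0) stop("noiseSd must be > 0")
  structure(list(nClasses = nClasses, classCounts = classCounts,
                 dim = dim, separation = as.numeric(separation),
                 submodesPerClass = submodesPerClass,
                 noiseSd = as.numeric(noiseSd),
                 seed = as.integer(seed)),
            class = "BlobSpec")
}

#' Power-law class-count profile
#'
#' `count_c` proportional to `rank^-exponent`, rescaled to `totalN` and
#' floored at 1; the residual after flooring is distributed by largest
#' fractional part so the counts sum to `totalN` exactly.
#'
#' @param nClasses number of classes
#' @param exponent power-law exponent (0 gives a balanced profile)
#' @param totalN total item count (must be >= nClasses)
#' @return integer vector of length `nClasses` summing to `totalN`
#' @export
powerLawCounts <- function(nClasses, exponent, totalN) {
  nClasses <- as.integer(nClasses); totalN <- as.integer(totalN)
  if (exponent < 0) stop("exponent must be >= 0")
  if (totalN < nClasses) stop("totalN must be >= nClasses")
  w <- seq_len(nClasses)^(-exponent)
  scaled <- w / sum(w) * totalN
  counts <- pmax(1L, as.integer(floor(scaled)))
  resid <- totalN - sum(counts)
  if (resid > 0) {
    ord <- order(scaled - floor(scaled), decreasing = TRUE)
    take <- rep_len(ord, resid)          # cycle if flooring left a big gap
    for (i in take) counts[i] <- counts[i] + 1L
  } else if (resid < 0) {
    # flooring at 1 overshot: shave from the largest classes
    while (resid < 0) {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
      resid <- resid + 1L
    }
  }
  counts
}

# random unit vector in d dimensions
.unitVector <- function(d) {
  v <- rnorm(d)
  n <- sqrt(sum(v^2))
  if (n == 0) v[1] <- 1 else v <- v / n
  v
}

#' Generate a synthetic embedding pool
#'
#' Draws the embedding cloud described by a [blobSpec()]: reproducible given
#' the spec's seed, with per-class item counts matching the requested counts
#' exactly. Item ids are zero-padded decimal strings in generation order, so
#' lexicographic and generation order coincide.
#'
#' @param spec a `BlobSpec`
#' @return a list with elements `embeddings` (an [EmbeddingSet-class]),
#'   `labels` (integer class index per item, 1-based) and `centers` (the
#'   true class centers, nClasses x dim)
#' @examples
#' pool <- generateBlobs(blobSpec(2, classCounts = c(5, 5), dim = 2,
#'                                separation = 10, seed = 7))
#' table(pool$labels)
#' @export
generateBlobs <- function(spec) {
  stopifnot(inherits(spec, "BlobSpec"))
  set.seed(spec$seed)
  C <- spec$nClasses; d <- spec$dim; S <- spec$submodesPerClass
  radius <- spec$separation * spec$noiseSd
  centers <- t(vapply(seq_len(C), function(i) radius * .unitVector(d),
                      numeric(d)))
  n <- sum(spec$classCounts)
  vals <- matrix(NA_real_, n, d)
  labels <- integer(n)
  row <- 0L
  for (c in seq_len(C)) {
    nc <- spec$classCounts[c]
    if (S == 1L) {
      sub <- matrix(centers[c, ], 1L, d, byrow = TRUE)
      subOf <- rep(1L, nc)
    } else {
      sub <- t(vapply(seq_len(S),
                      function(s) centers[c, ] + 0.5 * radius * .unitVector(d),
                      numeric(d)))
      subOf <- rep(seq_len(S), length.out = nc)
    }
    noise <- matrix(rnorm(nc * d, sd = spec$noiseSd), nc, d)
    vals[row + seq_len(nc), ] <- sub[subOf, , drop = FALSE] + noise
    labels[row + seq_len(nc)] <- c
    row <- row + nc
  }
  width <- max(6L, nchar(as.character(n)))
  ids <- sprintf(paste0("%0", width, "d"), seq_len(n))
  list(embeddings = EmbeddingSet(vals, ids = ids), labels = labels,
       centers = centers)
}

#' PlantVillage class-count profile
#'
#' Per-class image counts of the 38-class PlantVillage leaf-disease dataset
#' (14 crops, healthy and diseased leaves; 54,303 images in total). The
#' profile is strongly imbalanced — from 152 images (Potato healthy) to
#' 5,507 (Orange citrus greening) — and is used as the reference imbalance
#' profile for synthetic pools.
#'
#' @return named integer vector of length 38 summing to 54303
#' @export
plantVillageClassCounts <- function() {
  c("Apple scab" = 630L, "Apple black rot" = 621L,
    "Apple cedar rust" = 276L, "Apple healthy" = 1645L,
    "Blueberry healthy" = 1502L, "Cherry healthy" = 854L,
    "Cherry powdery mildew" = 1052L, "Corn cercospora" = 513L,
    "Corn rust" = 1192L, "Corn healthy" = 1162L,
    "Corn northern leaf blight" = 985L, "Grape black rot" = 1180L,
    "Grape black measles" = 1384L, "Grape healthy" = 423L,
    "Grape isariopsis leaf spot" = 1076L, "Orange citrus greening" = 5507L,
    "Peach bacterial spot" = 2291L, "Peach healthy" = 360L,
    "Pepper bacterial spot" = 997L, "Pepper healthy" = 1478L,
    "Potato early blight" = 1000L, "Potato healthy" = 152L,
    "Potato late blight" = 1000L, "Raspberry healthy" = 371L,
    "Soybean healthy" = 5090L, "Squash powdery mildew" = 1835L,
    "Strawberry healthy" = 456L, "Strawberry leaf scorch" = 1109L,
    "Tomato bacterial spot" = 2127L, "Tomato early blight" = 1000L,
    "Tomato healthy" = 1592L, "Tomato late blight" = 1910L,
    "Tomato leaf mold" = 952L, "Tomato septoria leaf spot" = 1771L,
    "Tomato spider mites" = 1676L, "Tomato target spot" = 1404L,
    "Tomato mosaic virus" = 373L, "Tomato yellow leaf curl" = 5357L)
}

#' Synthetic pool with the PlantVillage imbalance profile
#'
#' Convenience wrapper: a 38-class blob pool whose class counts are the
#' PlantVillage profile scaled down by `scale` (rounded, floored at 1),
#' giving a desk-scale stand-in for the real embedding cloud. Defaults
#' (dim 32, separation 8, unit noise) produce a well-separated
#' high-dimensional pool of 5,429 items at `scale = 10`.
#'
#' @param scale down-scaling divisor for the class counts
#' @param dim embedding dimensionality
#' @param separation inter-class spacing in within-class standard deviations
#' @param noiseSd within-class standard deviation
#' @param seed integer seed
#' @return as [generateBlobs()], plus `manifest` (labels as zero-padded
#'   class strings) and `classCounts`
#' @export
plantVillagePool <- function(scale = 10, dim = 32L, separation = 8,
                             noiseSd = 1, seed = 1L) {
  counts <- pmax(1L, as.integer(round(plantVillageClassCounts() / scale)))
  spec <- blobSpec(nClasses = length(counts), classCounts = counts,
                   dim = dim, separation = separation, noiseSd = noiseSd,
                   seed = seed)
  pool <- generateBlobs(spec)
  lab <- sprintf("class%02d", pool$labels)
  pool$manifest <- generateManifest(pool$embeddings, labels = lab)
  pool$classCounts <- counts
  pool
}
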