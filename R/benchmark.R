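#' Repeated-split benchmark: coreset vs random reduction
#'
#' Implements the evaluation protocol used to validate cluster-based
#' selection. For each repetition `r` (seed `baseSeed + r`):
#' 10% of the labeled pool is set aside as a fixed test set; the remaining
#' 90% becomes the unlabeled selection pool. For every retention fraction
#' and strategy, a coreset of `subsetSize(poolN, fraction)` items is
#' selected, split 90/10 into training and validation, a classifier is
#' trained on the training part (validation monitors best-epoch weights),
#' and macro-F1 is measured on the held-out test set over the classes
#' present in the test ground truth (absent classes are excluded).
#' Reported statistics are the mean and the sample standard deviation
#' (n - 1 denominator) across repetitions.
#'
#' @param x the pool [EmbeddingSet-class]
#' @param manifest labeled manifest covering the pool
#' @param fractions retention fractions to test, each in (0, 1]
#' @param strategies selection strategies (see [selectionPlan()])
#' @param repetitions number of repeated splits (default 3)
#' @param testFraction held-out test share (default 0.10)
#' @param valFraction validation share within the coreset (default 0.10)
#' @param baseSeed global seed; every stage derives from it
#' @param nClasses assumed class count for the class-based strategies
#'   (defaults to the number of labeled classes in the manifest)
#' @param trainer function(x, y, classLevels, seed, xVal, yVal) returning a
#'   model with a `predict(model, newdata)` method; defaults to
#'   [softmaxTrain()]
#' @param kmeansControl overrides for the selection clustering, see
#'   [selectCoreset()]
#' @return list with `details` (one row per fraction x strategy x
#'   repetition: `fraction`, `strategy`, `rep`, `m`, `classesEmpty`,
#'   `macroF1`) and `summary` (mean and sample-sd macro-F1 per
#'   fraction x strategy)
#' @export
runBenchmark <- function(x, manifest, fractions, strategies,
                         repetitions = 3L, testFraction = 0.10,
                         valFraction = 0.10, baseSeed = 1L,
                         nClasses = NULL, trainer = softmaxTrain,
                         kmeansControl = list()) {
  stopifnot(is(x, "EmbeddingSet"))
  validateManifest(manifest)
  if (!"label" %in% names(manifest)) stop("benchmark needs a labeled manifest")
  if (testFraction <= 0 || testFraction >= 1 ||
      valFraction < 0 || valFraction >= 1)
    stop("test and validation fractions must lie in (0, 1)")
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")

  ids <- itemIds(x)
  lab <- manifest$label[match(ids, manifest$id)]
  if (anyNA(lab)) stop("manifest must label every pool item")
  classLevels <- sort(unique(lab))
  if (is.null(nClasses)) nClasses <- length(classLevels)
  v <- embMatrix(x)

  details <- list()
  for (r in seq_len(repetitions)) {
    repSeed <- deriveSeed(baseSeed + r, "benchmark-rep")
    set.seed(deriveSeed(repSeed, "test-split"))
    nTest <- max(1L, floor(length(ids) * testFraction))
    testIdx <- sample.int(length(ids), nTest)
    poolIdx <- setdiff(seq_along(ids), testIdx)
    pool <- EmbeddingSet(v[poolIdx, , drop = FALSE])
    testX <- v[testIdx, , drop = FALSE]
    testY <- lab[testIdx]
    testClasses <- sort(unique(testY))

    for (f in fractions) {
      m <- subsetSize(length(poolIdx), f)
      if (m < 2L && valFraction > 0)
        stop(sprintf("fraction %g leaves no room for a validation split", f))
      for (strat in strategies) {
        plan <- selectionPlan(strat, m = m, nClasses = nClasses,
                              seed = deriveSeed(repSeed,
                                                paste0("select-", strat,
                                                       "-", f)))
        res <- selectCoreset(pool, plan, kmeansControl = kmeansControl)
        # sort so the train/val split depends only on the selected id set,
        # not on the order a strategy emits it (strategies selecting the
        # same items are then trained identically)
        selIdx <- sort(match(selectedIds(res), ids))
        cov <- classCoverage(res, manifest)

        set.seed(deriveSeed(repSeed, paste0("val-split-", f)))
        nVal <- if (valFraction > 0) max(1L, floor(m * valFraction)) else 0L
        valPick <- if (nVal > 0) sample.int(m, nVal) else integer(0)
        trainIdx <- selIdx[setdiff(seq_len(m), valPick)]
        valIdx <- selIdx[valPick]

        model <- trainer(v[trainIdx, , drop = FALSE], lab[trainIdx],
                         classLevels = classLevels,
                         seed = deriveSeed(repSeed, paste0("train-", f)),
                         xVal = if (nVal > 0) v[valIdx, , drop = FALSE],
                         yVal = if (nVal > 0) lab[valIdx])
        pred <- predict(model, testX)
        f1 <- macroF1(testY, pred, classSet = testClasses)
        details[[length(details) + 1L]] <-
          data.frame(fraction = f, strategy = strat, rep = r, m = m,
                     classesEmpty = cov$classesEmpty, macroF1 = f1,
                     stringsAsFactors = FALSE)
      }
    }
  }
  details <- do.call(rbind, details)
  summary <- do.call(rbind, lapply(
    split(details, list(details$fraction, details$strategy), drop = TRUE),
    function(g) data.frame(
      fraction = g$fraction[1L], strategy = g$strategy[1L],
      meanF1 = mean(g$macroF1),
      sdF1 = if (nrow(g) > 1L) sd(g$macroF1) else NA_real_,
      reps = nrow(g), stringsAsFactors = FALSE)))
  summary <- summary[order(summary$fraction, summary$strategy), ]
  rownames(summary) <- NULL
  list(details = details, summary = summary)
}
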