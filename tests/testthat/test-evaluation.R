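test_that("macro-F1 matches hand-computed confusion counts", {
  expect_equal(macroF1(c("A", "B"), c("A", "B")), 1.0)
  # F1_A = 2/3, F1_B = 0.8 -> macro 0.7333...
  f <- f1Scores(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(f$perClass), c(2 / 3, 0.8))
  expect_equal(f$macro, (2 / 3 + 0.8) / 2)
  expect_length(f$degenerate, 0L)
})

test_that("degenerate classes contribute 0 and are flagged", {
  f <- f1Scores(c("A", "A", "B"), c("A", "A", "B"),
                classSet = c("A", "B", "C"))
  expect_equal(unname(f$perClass["C"]), 0)
  expect_identical(f$degenerate, "C")
  expect_equal(f$macro, 2 / 3)
  expect_error(macroF1(character(0), character(0)), "empty")
  expect_error(macroF1(c("A", "Z"), c("A", "A"), classSet = "A"),
               "outside")
})

test_that("macro-F1 is relabel-invariant and bounded", {
  set.seed(4)
  for (i in 1:10) {
    yt <- sample(letters[1:4], 50, replace = TRUE)
    yp <- sample(letters[1:4], 50, replace = TRUE)
    m <- macroF1(yt, yp, classSet = letters[1:4])
    expect_gte(m, 0); expect_lte(m, 1)
    relab <- c(a = "w", b = "x", c = "y", d = "z")
    expect_equal(macroF1(relab[yt], relab[yp], classSet = relab[letters[1:4]]),
                 m)
  }
})

test_that("validity indices reproduce the hand-computed toy", {
  v <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  # S = 0.5 per group, centroid distance 10 -> DB = 0.1
  expect_equal(daviesBouldin(v, lab), 0.1, tolerance = 1e-12)
  # a = 1, b = (10 + sqrt(101)) / 2 for every point
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouetteScore(v, lab), (b - 1) / b, tolerance = 1e-12)
  expect_equal(silhouetteScore(v, lab), 0.9002, tolerance = 1e-4)

  expect_error(daviesBouldin(v, rep(1, 4)), "2 groups")
  expect_error(silhouetteScore(v, rep(1, 4)), "2 groups")
})

test_that("tight duplicate groups drive Davies-Bouldin toward 0", {
  v <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  expect_equal(daviesBouldin(v, rep(1:2, each = 3)), 0)
})

test_that("indices agree with brute-force implementations to 1e-9", {
  set.seed(202)
  for (i in 1:15) {
    n <- sample(20:80, 1)
    d <- sample(2:6, 1)
    g <- sample(2:5, 1)
    v <- matrix(rnorm(n * d), n, d)
    lab <- sample(g, n, replace = TRUE)
    while (length(unique(lab)) < 2) lab <- sample(g, n, replace = TRUE)
    expect_equal(daviesBouldin(v, lab), bruteDB(v, lab), tolerance = 1e-9)
    expect_equal(silhouetteScore(v, lab), bruteSilhouette(v, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(55)
  v <- matrix(rnorm(120), 60, 2)
  lab <- sample(3, 60, replace = TRUE)
  ref <- mean(cluster::silhouette(lab, stats::dist(v))[, "sil_width"])
  expect_equal(silhouetteScore(v, lab), ref, tolerance = 1e-9)
})

test_that("silhouette is near 0 for overlapping groups and relabel-safe", {
  set.seed(77)
  v <- matrix(rnorm(500 * 2), 500, 2)
  lab <- rep(1:2, 250)
  expect_lt(abs(silhouetteScore(v, lab)), 0.1)
  expect_equal(silhouetteScore(v, 3 - lab), silhouetteScore(v, lab))
  # singleton group scores 0 for its lone member
  v2 <- rbind(c(0, 0), c(0, 1), c(9, 9))
  expect_no_error(silhouetteScore(v2, c(1, 1, 2)))
})

test_that("class coverage counts selected items per ground-truth class", {
  pool <- generateBlobs(blobSpec(5, classCounts = rep(4L, 5), dim = 2,
                                 separation = 9, seed = 6))
  manifest <- generateManifest(pool$embeddings, labels = pool$labels)
  all20 <- randomSelect(itemIds(pool$embeddings), 20, seed = 1)
  cov <- classCoverage(all20, manifest)
  expect_equal(cov$classesEmpty, 0L)
  expect_equal(sum(cov$perClassCounts), 20L)

  # pigeonhole: 3 selected items cannot cover 5 classes
  three <- randomSelect(itemIds(pool$embeddings), 3, seed = 2)
  expect_gte(classCoverage(three, manifest)$classesEmpty, 2L)

  unlabeled <- manifest[, c("id", "uri")]
  expect_error(classCoverage(three, unlabeled), "labels")
  short <- manifest[1:5, ]
  expect_error(classCoverage(all20, short), "missing label")
})

test_that("evaluateSelection assembles coverage plus validity indices", {
  pool <- generateBlobs(blobSpec(3, classCounts = c(6, 6, 6), dim = 2,
                                 separation = 8, seed = 9))
  manifest <- generateManifest(pool$embeddings, labels = pool$labels)
  res <- selectCoreset(pool$embeddings,
                       selectionPlan("images", m = 6, seed = 2),
                       kmeansControl = list(nInit = 2))
  rep <- evaluateSelection(pool$embeddings, manifest, res)
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@perClassSelectedCounts), 6)
  expect_gte(rep@silhouette, -1); expect_lte(rep@silhouette, 1)
  expect_gte(rep@daviesBouldin, 0)
})
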