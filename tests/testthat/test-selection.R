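test_that("subset sizes reproduce the published reduction table", {
  # PlantVillage column: floor of 48875 * fraction
  pv <- c("0.3" = 146, "0.5" = 244, "1" = 488, "3" = 1466, "5" = 2443,
          "10" = 4887, "30" = 14662, "100" = 48875)
  for (pct in names(pv))
    expect_equal(subsetSize(48875, as.numeric(pct) / 100), pv[[pct]])
  # Flowers column: nearest rounding of 6633 * fraction
  fl <- c("3" = 199, "5" = 332, "7" = 464, "10" = 663, "15" = 995,
          "20" = 1327, "30" = 1990)
  for (pct in names(fl))
    expect_equal(subsetSize(6633, as.numeric(pct) / 100, "nearest"),
                 fl[[pct]])
  # 10% of the Flowers pool agrees under either convention
  expect_equal(subsetSize(6633, 0.10, "floor"), 663L)
  expect_equal(subsetSize(100, 1.0), 100L)
  expect_error(subsetSize(10, 0.01), "too small")
})

test_that("per-cluster quotas are balanced, capped and conserved", {
  a <- allocatePerCluster(146, rep(100L, 38))
  expect_equal(sum(a), 146L)
  expect_lte(max(a) - min(a), 1L)
  expect_equal(sum(a == 4L), 32L)  # 146 = 38 * 3 + 32

  expect_equal(allocatePerCluster(5, rep(10L, 5)), rep(1L, 5))
  expect_equal(allocatePerCluster(6, c(1L, 1L, 100L)), c(1L, 1L, 4L))
  expect_error(allocatePerCluster(10, c(3L, 3L)), "too small")

  set.seed(17)
  for (i in 1:20) {
    sizes <- sample.int(30, sample(2:8, 1), replace = TRUE)
    M <- sample.int(sum(sizes), 1)
    a <- allocatePerCluster(M, sizes)
    expect_equal(sum(a), M)
    expect_true(all(a <= sizes))
    expect_true(all(a >= 0L))
  }
})

test_that("selection plans validate their invariants", {
  expect_error(validObject(selectionPlan("images")), "exactly one")
  expect_error(validObject(selectionPlan("images", m = 2, fraction = 0.5)),
               "exactly one")
  expect_error(validObject(selectionPlan("classes", m = 5)), "nClasses")
  expect_error(validObject(selectionPlan("images", m = 0)), "positive")
  expect_error(validObject(selectionPlan("images", fraction = 1.5)),
               "fraction")
  expect_silent(validObject(selectionPlan("images", m = 3)))
})

test_that("K = M selection draws one item per cluster, one per true group", {
  for (seed in 1:20) {
    e <- twoGroupPool(seed = 100 + seed)
    res <- selectCoreset(e, selectionPlan("images", m = 2, seed = seed))
    expect_length(selectedIds(res), 2L)
    expect_equal(sort(provenance(res)), 1:2)  # one per cluster
    # the two tight groups are rows 1-5 and 6-10: one id from each
    groups <- ifelse(match(selectedIds(res), itemIds(e)) <= 5, "lo", "hi")
    expect_setequal(groups, c("lo", "hi"))
  }
})

test_that("class-count strategy draws balanced quotas from each cluster", {
  e <- twoGroupPool(seed = 1)
  res <- selectCoreset(e, selectionPlan("classes", m = 4, nClasses = 2,
                                        seed = 5))
  expect_length(selectedIds(res), 4L)
  expect_equal(unname(table(provenance(res))), c(2L, 2L),
               ignore_attr = TRUE)
  res2 <- selectCoreset(e, selectionPlan("2classes", m = 8, nClasses = 2,
                                         seed = 5))
  expect_equal(res2@kUsed, 4L)
  expect_length(selectedIds(res2), 8L)
})

test_that("selection size is conserved for every strategy", {
  pool <- generateBlobs(blobSpec(4, classCounts = c(20, 10, 5, 5), dim = 3,
                                 separation = 6, seed = 2))
  e <- pool$embeddings
  for (strat in c("images", "classes", "2classes", "random")) {
    res <- selectCoreset(e, selectionPlan(strat, m = 12, nClasses = 4,
                                          seed = 3),
                         kmeansControl = list(nInit = 2))
    expect_length(selectedIds(res), 12L)
    expect_false(anyDuplicated(selectedIds(res)) > 0)
    expect_true(all(selectedIds(res) %in% itemIds(e)))
  }
  # fraction-driven size resolution
  res <- selectCoreset(e, selectionPlan("random", fraction = 0.25, seed = 1))
  expect_length(selectedIds(res), 10L)  # floor(40 * 0.25)
})

test_that("infeasible selections are rejected", {
  e <- twoGroupPool()
  expect_error(selectCoreset(e, selectionPlan("images", m = 11, seed = 1)),
               "exceeds")
  expect_error(selectCoreset(e, selectionPlan("classes", m = 2, nClasses = 5,
                                              seed = 1)), "exceeds")
  expect_error(randomSelect(itemIds(e), 11), "exceeds")
  expect_error(randomSelect(itemIds(e), 0), "positive")
})

test_that("the random baseline is uniform and seed-deterministic", {
  ids <- c("a", "b", "c", "d")
  expect_setequal(selectedIds(randomSelect(ids, 4, seed = 9)), ids)

  # frequency of each id in 10,000 seeded draws of M = 1: binomial 4-sigma
  picks <- vapply(1:10000, function(s)
    selectedIds(randomSelect(ids, 1, seed = s)), character(1))
  freq <- table(factor(picks, levels = ids)) / 10000
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 4 * sigma))

  expect_identical(selectedIds(randomSelect(ids, 2, seed = 5)),
                   selectedIds(randomSelect(ids, 2, seed = 5)))
})

test_that("selection is reproducible from the plan seed alone", {
  e <- twoGroupPool(seed = 3)
  plan <- selectionPlan("images", m = 4, seed = 77)
  r1 <- selectCoreset(e, plan)
  r2 <- selectCoreset(e, plan)
  expect_identical(selectedIds(r1), selectedIds(r2))
  expect_identical(provenance(r1), provenance(r2))
})

test_that("nearest-to-centroid within-cluster sampling is supported", {
  e <- twoGroupPool(seed = 8)
  res <- selectCoreset(e, selectionPlan("classes", m = 2, nClasses = 2,
                                        seed = 1), within = "nearest")
  km <- kmeansFit(e, 2, seed = deriveSeed(1, "kmeans"))
  for (i in 1:2) {
    cl <- provenance(res)[i]
    members <- which(clusterAssignments(km) == cl)
    d2 <- rowSums((embMatrix(e)[members, , drop = FALSE] -
                   matrix(centroids(km)[cl, ], length(members), 2,
                          byrow = TRUE))^2)
    expect_equal(selectedIds(res)[i], itemIds(e)[members[which.min(d2)]])
  }
})
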