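test_that("the 4-point toy reaches the exhaustive-partition optimum", {
  v <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  e <- EmbeddingSet(v, ids = paste0("p", 1:4))
  m <- kmeansFit(e, 2, seed = 1)
  expect_equal(inertia(m), 1.0)
  expect_equal(exhaustiveInertia(v, 2), 1.0)
  # the two left points share a cluster, the two right points the other
  a <- clusterAssignments(m)
  expect_equal(a[1], a[2])
  expect_equal(a[3], a[4])
  expect_false(a[1] == a[3])
  expect_equal(sort(clusterSizes(m)), c(2L, 2L))
})

test_that("k = N gives singleton clusters, k = 1 the global mean", {
  set.seed(3)
  v <- matrix(rnorm(14), 7, 2)
  e <- EmbeddingSet(v, ids = letters[1:7])
  singletons <- kmeansFit(e, 7, seed = 2)
  expect_equal(inertia(singletons), 0)
  expect_equal(sort(clusterAssignments(singletons)), 1:7)

  one <- kmeansFit(e, 1, seed = 2)
  expect_equal(unname(centroids(one)[1, ]), unname(colMeans(v)))
  expect_equal(inertia(one), sum(scale(v, scale = FALSE)^2))
})

test_that("infeasible k is rejected", {
  e <- EmbeddingSet(matrix(rnorm(10), 5, 2), ids = letters[1:5])
  expect_error(kmeansFit(e, 6), "exceeds")
  expect_error(kmeansFit(e, 0), ">= 1")
})

test_that("model invariants hold on random fits", {
  set.seed(11)
  for (rep in 1:5) {
    v <- matrix(rnorm(60 * 3), 60, 3)
    e <- EmbeddingSet(v, ids = sprintf("i%02d", 1:60))
    m <- kmeansFit(e, 5, seed = rep)
    a <- clusterAssignments(m)
    # centroid = mean of members
    for (j in 1:5)
      expect_equal(unname(centroids(m)[j, ]),
                   unname(colMeans(v[a == j, , drop = FALSE])),
                   tolerance = 1e-9)
    # inertia consistent with assignment
    expect_equal(inertia(m), clusterInertia(e, centroids(m), a),
                 tolerance = 1e-9)
    # every item at its nearest centroid
    expect_equal(a, unname(bruteNearest(v, centroids(m))))
    # no empty cluster, sizes conserve N
    expect_true(all(clusterSizes(m) > 0L))
    expect_equal(sum(clusterSizes(m)), 60L)
    # Lloyd monotonicity
    expect_true(all(diff(m@trace) <= 1e-9))
  }
})

test_that("fits are bit-identical given the same seed", {
  e <- EmbeddingSet(matrix(rnorm(80), 40, 2), ids = sprintf("i%02d", 1:40))
  m1 <- kmeansFit(e, 4, seed = 7)
  m2 <- kmeansFit(e, 4, seed = 7)
  expect_identical(centroids(m1), centroids(m2))
  expect_identical(clusterAssignments(m1), clusterAssignments(m2))
  expect_identical(inertia(m1), inertia(m2))
})

test_that("row permutation only relabels the clustering", {
  set.seed(21)
  v <- matrix(rnorm(30 * 2), 30, 2)
  e <- EmbeddingSet(v, ids = sprintf("i%02d", 1:30))
  init <- v[c(1, 15, 30), ]
  m <- kmeansFit(e, 3, initCenters = init)
  perm <- sample(30)
  ep <- EmbeddingSet(v[perm, , drop = FALSE],
                     ids = sprintf("i%02d", 1:30)[perm])
  mp <- kmeansFit(ep, 3, initCenters = init)
  # same partition of the same items, up to cluster relabeling
  expect_identical(clusterAssignments(mp),
                   clusterAssignments(m)[perm])
  expect_equal(inertia(mp), inertia(m), tolerance = 1e-12)
})

test_that("assignment ties break toward the lowest cluster index", {
  centers <- rbind(c(0, 0), c(5, 5), c(2, 0))
  m <- kmeansFit(EmbeddingSet(centers, ids = c("a", "b", "c")), 3,
                 initCenters = centers)
  # (1, 0) is equidistant to centers 1 and 3
  expect_equal(assignToClusters(m, matrix(c(1, 0), 1, 2)), 1L)
  # a point equal to a centroid maps to it
  expect_equal(assignToClusters(m, matrix(c(5, 5), 1, 2)), 2L)
  expect_error(assignToClusters(m, matrix(0, 1, 3)), "mismatch")
})

test_that("assignment matches a brute-force nearest-centroid scan", {
  set.seed(5)
  v <- matrix(rnorm(100), 50, 2)
  e <- EmbeddingSet(v, ids = sprintf("i%02d", 1:50))
  m <- kmeansFit(e, 4, seed = 9)
  q <- matrix(rnorm(60), 30, 2)
  expect_equal(assignToClusters(m, q), unname(bruteNearest(q, centroids(m))))
})

test_that("clusterInertia matches hand values and validates input", {
  centers <- rbind(c(0, 0), c(1, 1))
  expect_equal(clusterInertia(rbind(c(0, 0), c(1, 1)), centers, c(1, 2)), 0)
  expect_equal(clusterInertia(matrix(c(2, 0), 1, 2), centers, 1L), 4)
  expect_error(clusterInertia(matrix(c(2, 0), 1, 2), centers, 3L),
               "out of range")
})

test_that("restarted fits match stats::kmeans quality on moderate data", {
  # independent cross-check: both should find partitions of equal quality
  set.seed(31)
  v <- matrix(rnorm(120 * 2), 120, 2) + rep(c(0, 6), each = 60)
  e <- EmbeddingSet(v, ids = sprintf("i%03d", 1:120))
  ours <- kmeansFit(e, 3, nInit = 10, seed = 1)
  ref <- stats::kmeans(v, 3, nstart = 10, iter.max = 100)
  expect_equal(inertia(ours), ref$tot.withinss, tolerance = 1e-6)
})

test_that("empty clusters are repaired when initialized degenerately", {
  # all-duplicate initial centers force empties at the first assignment
  v <- rbind(matrix(rnorm(20, sd = .2), 10, 2),
             matrix(rnorm(20, sd = .2) + 8, 10, 2))
  init <- v[c(1, 1, 1), ]
  m <- kmeansFit(EmbeddingSet(v, ids = sprintf("i%02d", 1:20)), 3,
                 initCenters = init)
  expect_true(all(clusterSizes(m) > 0L))
  expect_equal(sum(clusterSizes(m)), 20L)
})
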