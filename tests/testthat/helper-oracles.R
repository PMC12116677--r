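# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package: plain loops and
# enumeration only.

# Global minimum of the K-means objective by enumerating all k^N assignments
# (each cluster's centroid is the mean of its members).
exhaustiveInertia <- function(v, k) {
  n <- nrow(v)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  Q <- sum(v^2)
  best <- Inf
  # vectorized over assignments: inertia = Q - sum_c ||sum_c||^2 / n_c
  explained <- 0
  for (c in seq_len(k)) {
    mask <- (grid == c) * 1
    counts <- rowSums(mask)
    S <- mask %*% v
    term <- rowSums(S^2)
    term[counts > 0] <- term[counts > 0] / counts[counts > 0]
    term[counts == 0] <- 0
    explained <- explained + term
  }
  min(Q - explained)
}

# Davies-Bouldin by direct loops over the printed formula.
bruteDB <- function(v, labels) {
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  g <- length(gs)
  cent <- matrix(NA_real_, g, ncol(v))
  s <- numeric(g)
  for (i in seq_len(g)) {
    rows <- v[labels == gs[i], , drop = FALSE]
    cent[i, ] <- colMeans(rows)
    dd <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows)))
      dd[r] <- sqrt(sum((rows[r, ] - cent[i, ])^2))
    s[i] <- mean(dd)
  }
  total <- 0
  for (i in seq_len(g)) {
    worst <- -Inf
    for (j in seq_len(g)) {
      if (j == i) next
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      worst <- max(worst, (s[i] + s[j]) / m)
    }
    total <- total + worst
  }
  total / g
}

# Mean silhouette by direct loops (pairwise distances computed row by row).
bruteSilhouette <- function(v, labels) {
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  n <- nrow(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((v - matrix(v[i, ], n, ncol(v), byrow = TRUE))^2))
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(di[own])
    b <- Inf
    for (g in setdiff(gs, labels[i]))
      b <- min(b, mean(di[labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Nearest centroid by O(N*k) scan, ties to the lowest index.
bruteNearest <- function(v, centers) {
  apply(v, 1, function(x) {
    d2 <- colSums((t(centers) - x)^2)
    which.min(d2)
  })
}

# Two tight, well-separated groups of 5 points in 2-D.
twoGroupPool <- function(seed = 42, separation = 10) {
  set.seed(seed)
  v <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2),
             matrix(rnorm(10, sd = 0.1) + separation, 5, 2))
  EmbeddingSet(v, ids = sprintf("g%02d", 1:10))
}
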