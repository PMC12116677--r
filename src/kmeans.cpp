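#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Squared Euclidean distance between row i of X and row j of C.
// Both matrices are column-major (R layout): stride = number of rows.
static inline double rowSqDist(const double *X, int n, int i,
                               const double *C, int k, int j, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = X[(size_t)c * n + i] - C[(size_t)c * k + j];
    s += diff * diff;
  }
  return s;
}

// k-means++ seeding. Uses R's RNG (unif_rand) so results are reproducible
// under set.seed() from the R side.
// [[Rcpp::export]]
NumericMatrix cpp_kmeanspp(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  const double *x = X.begin();
  NumericMatrix centers(k, d);
  std::vector<double> d2(n, std::numeric_limits<double>::infinity());
  std::vector<bool> chosen(n, false);

  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  std::vector<int> idx(k);
  idx[0] = first;
  chosen[first] = true;

  for (int j = 1; j < k; ++j) {
    // update D^2 against the most recently added center
    int prev = idx[j - 1];
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = x[(size_t)c * n + i] - x[(size_t)c * n + prev];
        s += diff * diff;
      }
      if (s < d2[i]) d2[i] = s;
      total += d2[i];
    }
    int pick = -1;
    if (total > 0.0) {
      double r = unif_rand() * total, cum = 0.0;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (cum >= r) { pick = i; break; }
      }
      if (pick < 0) pick = n - 1;
    } else {
      // all remaining points coincide with chosen centers: pick the first
      // unchosen index (deterministic)
      for (int i = 0; i < n; ++i) if (!chosen[i]) { pick = i; break; }
      if (pick < 0) pick = (int)std::floor(unif_rand() * n);
    }
    idx[j] = pick;
    chosen[pick] = true;
  }
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c)
      centers(j, c) = X(idx[j], c);
  return centers;
}

// One Lloyd run from explicit initial centers.
// Convergence: assignments unchanged (full fixed point) or relative inertia
// improvement < tol or maxIter. Empty clusters are repaired by reseeding at
// the point currently farthest from its assigned centroid (deterministic).
// Returned centroids are exact means of the final assignment and the returned
// inertia is computed against them, so the model invariants hold by
// construction; ties in the assignment step go to the lowest cluster index.
// [[Rcpp::export]]
List cpp_lloyd(NumericMatrix X, NumericMatrix init, int maxIter, double tol) {
  const int n = X.nrow(), d = X.ncol(), k = init.nrow();
  NumericMatrix centers = clone(init);
  const double *x = X.begin();
  std::vector<int> assign(n, -1), prev(n, -2);
  std::vector<double> trace;
  trace.reserve(32);
  std::vector<int> sizes(k, 0);
  double prevInertia = std::numeric_limits<double>::infinity();
  int iter = 0;
  bool stable = false;

  for (iter = 1; iter <= maxIter; ++iter) {
    // assignment step
    double inertia = 0.0;
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double s = rowSqDist(x, n, i, centers.begin(), k, j, d);
        if (s < best) { best = s; bj = j; }
      }
      assign[i] = bj;
      inertia += best;
    }
    for (int i = 0; i < n; ++i) sizes[assign[i]]++;

    // empty-cluster repair: move the globally farthest point into each
    // empty cluster, one at a time
    for (int j = 0; j < k; ++j) {
      if (sizes[j] > 0) continue;
      double worst = -1.0;
      int wi = -1;
      for (int i = 0; i < n; ++i) {
        if (sizes[assign[i]] <= 1) continue; // do not empty another cluster
        double s = rowSqDist(x, n, i, centers.begin(), k, assign[i], d);
        if (s > worst) { worst = s; wi = i; }
      }
      if (wi >= 0) {
        sizes[assign[wi]]--;
        assign[wi] = j;
        sizes[j] = 1;
      }
    }
    trace.push_back(inertia);

    stable = true;
    for (int i = 0; i < n; ++i)
      if (assign[i] != prev[i]) { stable = false; break; }
    if (stable) break;
    prev = assign;

    // update step: centroids = means of members
    std::fill(centers.begin(), centers.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < d; ++c)
        centers(assign[i], c) += X(i, c);
    for (int j = 0; j < k; ++j)
      if (sizes[j] > 0)
        for (int c = 0; c < d; ++c)
          centers(j, c) /= sizes[j];

    if (R_finite(prevInertia) && prevInertia > 0.0 &&
        (prevInertia - inertia) < tol * prevInertia) {
      break;
    }
    prevInertia = inertia;
  }
  if (iter > maxIter) iter = maxIter;

  // finalize: centroids = exact means of final assignment, inertia against
  // them (consistent state even when stopped on tol/maxIter)
  std::fill(centers.begin(), centers.end(), 0.0);
  std::fill(sizes.begin(), sizes.end(), 0);
  for (int i = 0; i < n; ++i) sizes[assign[i]]++;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c)
      centers(assign[i], c) += X(i, c);
  for (int j = 0; j < k; ++j)
    if (sizes[j] > 0)
      for (int c = 0; c < d; ++c)
        centers(j, c) /= sizes[j];
  double inertia = 0.0;
  for (int i = 0; i < n; ++i)
    inertia += rowSqDist(x, n, i, centers.begin(), k, assign[i], d);
  trace.push_back(inertia);

  IntegerVector a(n);
  for (int i = 0; i < n; ++i) a[i] = assign[i] + 1;
  IntegerVector sz(k);
  for (int j = 0; j < k; ++j) sz[j] = sizes[j];
  return List::create(_["centroids"] = centers,
                      _["assignments"] = a,
                      _["inertia"] = inertia,
                      _["iters"] = iter,
                      _["sizes"] = sz,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = stable);
}

// Nearest-centroid assignment (ties to the lowest index).
// [[Rcpp::export]]
IntegerVector cpp_assign(NumericMatrix X, NumericMatrix centers) {
  const int n = X.nrow(), d = X.ncol(), k = centers.nrow();
  IntegerVector a(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = rowSqDist(X.begin(), n, i, centers.begin(), k, j, d);
      if (s < best) { best = s; bj = j; }
    }
    a[i] = bj + 1;
  }
  return a;
}
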