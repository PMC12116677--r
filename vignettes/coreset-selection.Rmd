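---
title: "Unsupervised coreset selection from image embeddings"
author: "coresel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised coreset selection from image embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresel)
```

## The problem

In applied image classification — plant disease diagnosis is the motivating
case — images are cheap to collect but expensive to annotate: labels need
expert knowledge. Given a large unlabeled pool of $N$ images and an
annotation budget of $M \ll N$ labels, which $M$ images should be sent to
the annotators? A uniform random draw wastes budget on redundant images
and, under the heavy class imbalance typical of field data, routinely
leaves rare classes with **zero** annotated examples, which pins their
downstream F1 at 0.

`coresel` implements a simple, fully unsupervised alternative. Each image
is represented by an embedding — the feature vector a pre-trained
self-supervised backbone (e.g. a DINOv2 vision transformer) produces. The
pool of embeddings is partitioned with K-means, and the coreset is drawn
from the clusters, so every region of embedding space contributes to the
annotated set. When classes are separable in embedding space, clusters
align with classes and sub-modes of classes, and cluster-stratified
sampling becomes class-stratified sampling *without ever seeing a label*.

## The method

K-means minimizes the inertia
$\sum_{i=1}^{N} \lVert x_i - c_{a(i)} \rVert^2$ over assignments $a$ and
centroids $c_1, \dots, c_K$. Three choices of $K$ are supported, plus the
baseline:

* **`images`** — $K = M$: one cluster per coreset slot, one item drawn
  uniformly from each cluster. This maximizes the spread of the selection
  and is the strongest configuration in practice.
* **`classes`** / **`2classes`** — $K$ equal to (twice) the assumed class
  count, with per-cluster quotas of approximately $M/K$ from
  `allocatePerCluster()`.
* **`random`** — uniform selection without replacement, the baseline every
  strategy is benchmarked against.

The per-cluster allocation uses base quota $\lfloor M/K \rfloor$ with one
extra item for the $M \bmod K$ largest clusters (ties broken by cluster
index); quotas are capped at cluster sizes and any deficit is redistributed
one item at a time to the largest remaining capacity. Within a cluster,
sampling is uniform (a nearest-to-centroid variant is available but not the
default, since uniform draws preserve within-cluster variability).

Budgets are expressed either as a size $M$ or as a retention fraction of
the pool; `subsetSize()` converts fractions with a `floor` convention by
default (truncation reproduces the published 48,875-item reduction ladder:
0.3% → 146, 5% → 2443, 30% → 14662) and a `nearest` convention
(half-away-from-zero, which reproduces the published 6,633-item ladder,
e.g. 30% → 1990). The two published tables are internally inconsistent in
their rounding, so both conventions are exposed and the default is the
truncating one.

## The K-means engine

The clusterer is written in the package (Lloyd iteration and k-means++
seeding in compiled code, everything else in R) rather than delegated,
because its exact behavior is part of the method's contract:

* **Initialization** — k-means++ by default, `nInit = 10` restarts, best
  model by inertia. Restarts reduce the run-to-run variance that repeated
  benchmark splits average over.
* **Convergence** — stop at an assignment fixed point, when the relative
  inertia improvement falls below `tol = 1e-4`, or at `maxIter = 300`.
  Returned centroids are always the exact means of the final assignment
  and the reported inertia is computed against them, so the model
  invariants (centroid = member mean, inertia consistent, assignment
  nearest-centroid with ties to the lowest index) hold by construction at
  a fixed point.
* **Empty clusters** — reseeded deterministically at the point farthest
  from its assigned centroid; selection strategies require all $K$
  clusters non-empty.
* **Determinism** — all randomness (including inside the compiled seeding)
  flows through R's RNG, so a fit is bit-reproducible from its seed. Every
  pipeline stage derives its seed from the global seed by hashing the
  stage name (`deriveSeed()`), which keeps stages reproducible in
  isolation and avoids seed collisions.
* **Distance** — squared Euclidean on raw embeddings. `l2Normalize()` is
  available but off by default; the clustering contract is defined on the
  raw feature space.

The test suite checks this engine against an independent brute-force
oracle: on pools small enough to enumerate every partition
($N \le 10$, $k \le 3$), best-of-20-restart fits attain the global optimum
of the objective in ≥ 95 of 100 random instances and can never beat it;
Lloyd's inertia trace is checked to be non-increasing on every run.

## Evaluation machinery

* **Macro-averaged F1** (`macroF1()`) — the unweighted mean over classes of
  the per-class harmonic mean of precision and recall. Macro averaging is
  deliberate: under imbalance it exposes empty rare classes, which
  frequency-weighted scores hide. A class with zero precision + recall
  contributes 0; classes absent from both truth and prediction are flagged
  as degenerate. The benchmark averages over the classes present in each
  test split's ground truth — classes missing from a split are excluded
  rather than imputed.
* **Davies-Bouldin and silhouette** (`daviesBouldin()`,
  `silhouetteScore()`) — computed on the true class labels they quantify
  how separable the classes are in a given embedding space, i.e. how good
  a feature extractor is for this method. Both use Euclidean distance,
  matching the clustering metric; items in singleton groups receive
  silhouette 0. Both are verified to $10^{-9}$ against independently coded
  brute-force implementations, and on a hand-computable 4-point toy
  (Davies-Bouldin exactly 0.1, silhouette $(b-1)/b \approx 0.9002$ with
  $b = (10 + \sqrt{101})/2$).
* **Class coverage** (`classCoverage()`) — per-class selected counts and
  the number of classes with no selected item.
* **Repeated-split benchmark** (`runBenchmark()`) — per repetition: set
  aside 10% of the pool as the test set, reduce the remaining 90% by each
  strategy and fraction, split each coreset 90/10 into train/validation,
  train a classifier, and score macro-F1 on the test set; report mean and
  sample standard deviation (n − 1) across repetitions (three by default).
  The train/validation split is made on the sorted selected ids, so
  strategies that select the same items train identically.

The benchmark classifier is a multinomial linear (softmax) model trained by
full-batch gradient descent on the embedding vectors — 200 epochs, step
0.1, seeded initialization, best-validation-loss weights kept. This is a
desk-scale stand-in for fine-tuning an image CNN: it runs in seconds on a
CPU, is fully deterministic, and preserves the property the benchmark
measures (a class with no training items cannot be predicted well). The
trainer is a contract argument, so an image-based trainer can be dropped
in.

## The synthetic pool

Real embedding pools require image downloads and a GPU backbone, so the
package ships a generator that emulates the *statistical* structure the
method relies on:

* each class is an isotropic Gaussian mode (optionally several sub-modes
  per class, offset by half the placement radius, to mimic intra-class
  variability);
* class centers are placed uniformly on a hypersphere of radius
  `separation × noiseSd`, so one knob sets the ratio of between-class
  spacing to within-class spread;
* class counts follow either an explicit profile or a one-parameter
  power law (`powerLawCounts()`).

The reference pool (`plantVillagePool()`) uses the published 38-class
PlantVillage count profile — 54,303 leaf images, from 152 (Potato healthy)
to 5,507 (Orange citrus greening) per class — scaled down 10× to
$N = 5429$ so the full benchmark runs on one CPU in minutes. Defaults
chosen once for this pool: dimension 32 (large enough for high-dimensional
geometry — random class directions are nearly orthogonal, so separation
acts along essentially independent axes, as it does for real transformer
embeddings — while keeping distance computations cheap), separation 8,
unit noise, one sub-mode per class. At separation 8 a nearest-class-mean
classifier exceeds 99% accuracy on the generated data (checked by
simulation), matching the regime where a strong feature extractor makes
classes cleanly separable.

What the generator does **not** model: pixel-level appearance, embedding
anisotropy and curvature, heavy-tailed within-class structure, and
label noise. Tests passing on synthetic pools therefore demonstrate the
selection logic and its coverage behavior under imbalance, not absolute
F1 levels on real datasets.

## What the shipped experiments show

With the scaled PlantVillage-profile pool at separation 8:

* **Coverage** — at $M = 146$ (the published smallest budget), the
  $K = M$ coreset covers all 38 classes in essentially every seed, while
  random selection leaves one or more classes empty in the majority of
  seeds (several on average). This mirrors the published analysis in which
  random reduction left five classes without a single selected image.
* **Benchmark** — the coreset strategy's macro-F1 matches or beats random
  at every fraction tested in the mean, with the advantage concentrated at
  small retention fractions and vanishing as the fraction grows — the
  published qualitative shape.

Problem sizes used by the shipped acceptance checks (the package's own
desk-scale choices): 100 selection seeds for the coverage comparison with
one k-means++ restart per fit, 20 seeds × one repetition for the
benchmark, oracle checks on 100 enumerable instances and 50 brute-force
index instances.

## Known limitations

* **The $M < C$ regime.** At 0.3% retention of the scaled pool the budget
  is $M = 14$ items against $C = 38$ classes, so *no* selection method can
  cover every class and the achievable macro-F1 advantage of the coreset
  is capped; the measured advantage peaks at 1% ($M = 48$) instead of at
  the smallest fraction. The published experiments never enter this
  regime — their smallest budget is ~3.8 items per class. Consequently the
  coreset-minus-random gap on the scaled pool is non-increasing across
  1% → 5% → 30% and falls back between 0.3% and 1%; the gap-vs-fraction
  trend is negative (Spearman) but not monotone over the full ladder.
  Interpreting budgets below one item per class requires care in any
  deployment of this method.
* The gap between strategies narrows as separation decreases; with a weak
  feature extractor (low separation, negative silhouette), clusters stop
  aligning with classes and cluster-stratified sampling loses its
  advantage — consistent with the published backbone comparison, where a
  convolutional extractor's coreset did not beat random selection.
* `silhouetteScore()` materializes the full pairwise distance matrix
  ($O(N^2)$ memory); disable validity indices in `evaluateSelection()`
  for pools beyond a few tens of thousands of items.
* K-means with $K = M$ at large $M$ (thousands of clusters) is the
  computational bottleneck of the `images` strategy; the implementation is
  exact Lloyd, not a mini-batch approximation.

## Reproducing

`scripts/acceptance.R --seed <s> --out <path>` re-runs the pipeline end to
end — reduction-table arithmetic, toy validity indices, the enumeration
oracle, the 100-seed coverage comparison and the 10-seed benchmark — and
writes the resulting numbers as JSON. The test suite
(`tests/testthat/`) carries the full property and oracle checks described
above.
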