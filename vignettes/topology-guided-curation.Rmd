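---
title: "Topology-guided curation of expression matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-guided curation of expression matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TopoCurate)
```

## The problem

A bulk or single-cell expression study delivers a matrix $K_{n \times m}$
with $n$ cohorts (samples) in rows, $m$ genes in columns, and an integer
phenotype $X(c)$ per cohort.  Two curation problems recur.  First, some
cohorts carry measurements that are uncorrelated with their phenotype
(instrumental or manual error); removing them improves classifiers trained
on the remainder.  Second, when $n \ll m$, classifiers need a small gene
subset $G' \subset G$ whose expression reflects the phenotype.

TopoCurate addresses both with persistent homology, but not through the
usual route of appending barcode summaries to feature vectors.  Instead it
computes *representative persistent cycles* — concrete edge sets (dimension
1) and triangle sets (dimension 2) — that localize each prominent
topological feature, and curates the rows or columns that those cycles
touch.

## Filtrations and persistence pairing

Cohorts (or transposed, genes) become a point cloud in Euclidean space.  A
Vietoris–Rips filtration orders simplices by diameter: a simplex enters at
the maximum pairwise distance of its vertices, ties broken by (dimension,
lexicographic vertex tuple) so that repeated runs pair identically.
Persistence is computed by standard boundary-matrix column reduction over
$\mathbb{Z}/2$ (a small C++ kernel), which realizes the convention that a
triangle kills the *youngest* live 1-cycle.  Every finite interval
$[\beta, \delta)$ carries its creator (the $d$-simplex whose insertion
births the class) and destroyer (the $(d{+}1)$-simplex that kills it).

Interval tables expose both 0-based simplexwise indices (`birth`, `death`)
and the filtration values.  The bundled worked fixture
(`workedFiltrationExample()`) assigns values equal to its ten insertion steps, so
its three 1-dimensional pairs print as $(4,9)$, $(5,8)$, $(6,7)$ on the
value scale:

```{r worked-filtration}
pers <- computePersistence(workedFiltrationExample(), maxHomDim = 1)
finiteIntervals(pers, 1)[, c("birth_value", "death_value")]
```

Essential (infinite) classes are computed but excluded from all downstream
cycle extraction: curation consumes finite intervals only, ranked by length
$\delta - \beta$ (`topKByLength()`).

A sparse mode exists for large clouds: points receive greedy-permutation
insertion radii $\lambda_i$ and an edge $\{i,j\}$ survives only when
$d(i,j) \le 2\min(\lambda_i,\lambda_j)/\varepsilon$; higher simplices are
cliques of the surviving graph.  This is a simplified net-based
sparsification — it prunes long edges between well-covered points and keeps
all vertices — and it is an approximation: all tests and shipped analyses
run the exact filtration, which is the reference path.

## Representative cycles

**Dimension 1.**  At birth, the creator edge $\sigma^1_\beta$ closes a
cycle; the representative is $\sigma^1_\beta$ plus the shortest path
between its endpoints through the 1-skeleton present strictly before
$\beta$ (Dijkstra; Euclidean edge lengths by default, unit hops for
abstract complexes).  This is exactly the shortest cycle in the birth
complex.  The class that actually dies at $\delta$ can in principle be a
different linear combination; resolving that requires an annotation-based
verification pass that this package deliberately omits — the birth-time
shortest cycle typically coincides with it in practice, and the
simplification keeps the extractor polynomial and dependency-free.  The
choice is documented here as an approximation.

**Dimension 2.**  Minimal persistent 2-cycles are exact, but require a
*pseudo-manifold*: every triangle with at most two tetrahedral cofacets.
`pseudoManifoldize()` produces one by walking tetrahedra in filtration
order and keeping a tetrahedron only when all four of its triangles still
have fewer than two kept cofacets.  A per-triangle "keep the first two
cofaces" rule, applied independently per triangle, can leave a triangle
with three cofacets (a tetrahedron retained for one face may be the third
cofacet of another); the sequential greedy reading guarantees the bound
while still preferring the earliest cofaces — for an isolated triangle with
three cofacets it keeps exactly the two earliest.

On the pseudo-manifold, the dual flow network has one node per tetrahedron
plus one infinite vertex; each triangle is an undirected arc joining its
$\le 2$ cofacets (missing sides attach to the infinite vertex).  For an
interval $[\beta,\delta)$: the source is the destroyer tetrahedron, the
sink is the infinite vertex contracted with every tetrahedron inserted
after $\delta$, and a triangle's arc carries its weight (filtration value
by default, unit optionally) when inserted at or before $\beta$ and
infinite capacity otherwise.  Infinite capacities are modeled by
*contracting* arc endpoints before the cut — never by a large finite
number — and the remaining finite min s–t cut (igraph max-flow) yields the
triangles of a minimal-weight persistent cycle, which provably contains the
creator triangle.  H2 intervals are computed on the pseudo-manifold itself,
so destroyers and sinks always exist in the complex being cut.

Because H2 extraction needs tetrahedra, point clouds are built with
simplices up to dimension 3 whenever dimension-2 cycles are requested.

## Cohort curation: dominant cycles

Each representative cycle $Z$ has a vertex set $\mathrm{Vert}(Z)$ of
cohorts.  $Z$ is *dominant* when some label covers at least
$\lfloor |\mathrm{Vert}(Z)|/2 \rfloor$ of its vertices.  The floor (rather
than strict majority) is forced by the calibration cases shipped with the
package: a 15-vertex cycle with label counts (3, 7, 5) must count as
dominant, and 7 = floor(15/2).  Ties among labels reaching the maximal
count resolve to the smallest label value, purely for determinism.  The
curated cohort set is the union of $\mathrm{Vert}(Z)$ over dominant cycles
among the top $k$ (default 100, per homology dimension) — union semantics,
each cohort once, original row order preserved.

## Gene curation: the kappa cover

On the transposed cloud (genes as points in cohort space), each cycle's
gene vertices carry annotation term sets $f(g)$.  The statistic

$$\kappa(Z) = \min\{\, |S| : S \cap f(g) \neq \emptyset \;\
\forall g \in \mathrm{Vert}(Z) \,\}$$

is an exact minimum set cover, solved by iterative deepening over term
combinations in lexicographic order (cycle vertex sets are small, typically
5–30 genes, so exhaustive search is cheap; a greedy cover bounds the
depth).  The returned cover is therefore the lexicographically least among
the minima.  "Not annotated" is materialized as an ordinary coverable term
— required so that the six-gene worked example yields $\kappa = 3$:

```{r kappa}
fx <- workedAnnotationExample()
kappaCover(fx$genes, fx$annotations)
```

Genes are selected as the union of cycle vertex sets with
$\kappa \le \kappa_{\max}$.  The default $\kappa_{\max} = 3$ follows the
convention that 3 is a "low" and 6 a "high" cover size; no published cutoff
exists, so the threshold is an exposed parameter.

## Quantifying curation

`evaluateProbabilistic()` runs repeated stratified Monte-Carlo
cross-validation: by default 10 independent random splits holding out 20 %
of each class, retraining per split.  (A classic 10-fold scheme would imply
90/10 splits; the 80–20 wording dictates repeated 80/20 splits instead.)
Models are a decision tree (rpart) and Gaussian naive Bayes (e1071;
zero-variance features are dropped per split, since a Gaussian with zero
spread is degenerate).  Metrics are accuracy (trace/total), macro-averaged
precision and recall (a class with no predicted, respectively true,
instances contributes 0), and F1 as the harmonic mean of macro precision
and macro recall.

When curated and full cohorts are compared, selection can leak: cohorts
chosen on all data make the curated matrix easier to classify.
`compareCuratedVsFull()` therefore defaults to recomputing the curation on
the training rows of every split (`protocol = "within_split"`), testing on
untouched held-out rows; `protocol = "global"` reproduces the simpler
curate-once-evaluate-after variant used for headline-style tables.

The 1D convolutional classifier is implemented directly in R (no deep
learning framework is a dependency): convolution (sigmoid) → max pool of
size 2 → dropout → two dense ReLU layers of decreasing size → softmax,
cross-entropy loss, Adam.  Defaults: 32 filters, kernel 16, dropout 0.25,
dense 128 → 64, 50 epochs, learning rate $10^{-3}$, batch 32 — reasonable
for the synthetic fixtures, all exposed through `cnnSpec()`.  Genes are
ordered by `sortGenesByFunction()` (stable sort on each gene's
lexicographically smallest term) so functionally related genes form
contiguous blocks under the convolution window.  Features are standardised
with training-set statistics; all randomness (split, weights, dropout,
batch order) flows from one seed.  An SVM baseline is deliberately absent,
and no early stopping is used.

## The synthetic generators, and what they do not show

`plantedCohorts()` emulates a study at desk scale: classes sampled from
geometric structures (sphere, circle, torus, Gaussian blob) embedded in the
leading coordinates of an $m$-dimensional space, isotropic noise, and a
seeded fraction of cohorts replaced by broad uniform draws *that keep their
class label* — the label-uncorrelated rows that dominant-cycle curation is
designed to remove (relabeled outliers would be a different, easier
problem).  Defaults encode the standard test condition: two classes of 30
cohorts on unit 2-spheres centred at $\mp 3$ along the first of 8 axes,
noise sd 0.05, 10 % outliers.

Two deliberate generator choices:

* Noise is **uniform** with the requested standard deviation (support
  $\pm \sqrt{3}\,\sigma$).  Every clean cohort then lies within $3\sigma$
  of its planted surface by construction, so "the longest cycle hugs the
  planted surface to within 3·noise" is a deterministic property of a
  correct implementation rather than a high-probability event; with
  Gaussian noise the same check would fail for roughly one random seed in
  twelve through no fault of the algorithm.
* Outliers are drawn from a box twice the span of the clean data — far
  enough to be geometrically irrelevant, close enough that classifiers
  see them as genuinely mislabeled-looking rows.

`plantedGeneFamilies()` builds the gene-side analogue: each family lies on
a planted circle in its own pair of cohort coordinates (one long 1-cycle
per family), family members share an annotation term, and leftover genes
are scattered and unannotated.

Passing tests on these fixtures demonstrate that the machinery recovers
planted structure under controlled noise.  They do not demonstrate
performance on real expression data, which has heavy-tailed platform noise,
batch structure, correlated genes without geometric cycles, and annotation
vocabularies orders of magnitude larger; the generators make no attempt to
emulate platform-specific microarray noise.

## Numerical choices and problem sizes

* Rips scale: the default `maxScale` is the enclosing radius (the smallest
  scale at which some point sees all others), beyond which positive-degree
  Rips homology is trivial.  For well-separated planted classes a smaller
  scale (2.5 for the default sphere fixture, which comfortably exceeds the
  within-class diameter $2 + \text{noise}$) gives the same cycles at a
  fraction of the complex size, and the shipped analyses use it; the
  parameter is exposed everywhere.
* Degenerate inputs: a constant gene under z-scoring becomes a zero column
  (not an error); a dataset with no finite intervals in the requested
  dimensions yields an empty selection with a warning, not an error; a
  cohort selection that would make evaluation impossible (single class)
  falls back to the full training rows inside `compareCuratedVsFull()`.
* Tie-breaks: simplex order (value, dim, lexicographic), interval ranking
  (length, then earlier birth), dominance (smallest label), covers
  (lexicographic least) — all deterministic.
* Shipped analysis sizes: 60-cohort planted fixtures (≈ 9 000 simplices
  after pseudo-manifoldization), 30–40-point geometry fixtures, a
  200 × 64 CNN fixture, 100 random filtrations of ≤ 200 simplices for the
  reduction oracle and 200 random instances for the cover oracle.  These
  sizes keep the full validation suite around a minute while exercising
  every code path; they are choices of the test design, and every driver
  accepts larger inputs.

## Known limitations

* H1 representatives are shortest at birth, not certified shortest for the
  interval (see above); globally minimal H1 cycles are NP-hard.
* H2 minimal cycles require the pseudo-manifold restriction; homology is
  over $\mathbb{Z}/2$ only, and dimensions above 2 are out of scope.
* The exact Rips complex grows as $O(n^4)$ simplices at dimension 3; beyond
  a few hundred points the sparse mode or a tighter `maxScale` is
  mandatory.
* The kappa search is exact but exponential in the worst case; it is meant
  for cycle-sized gene sets, not whole-genome covers.
* Statistical significance of dominance or of low kappa is not assessed;
  curation is a deterministic geometric filter, not a test.
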