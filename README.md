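# TopoCurate

Topology-guided curation of gene expression matrices for phenotype
classification.

## The problem

An expression study is a matrix *K*<sub>n×m</sub> — *n* cohorts (samples)
in rows, *m* genes in columns — with an integer phenotype label per cohort.
Two things routinely degrade classifiers trained on it: cohorts whose
measurements are uncorrelated with their phenotype (instrumental or manual
error), and, when *n* ≪ *m*, the sheer width of the gene pool.  TopoCurate
curates both sides of the matrix using persistent homology — not the usual
barcode-as-feature-vector route, but *representative persistent cycles*,
concrete edge sets and triangle sets that localize each topological feature
and therefore map back to specific cohorts or genes.

## The method

* **Filtration and pairing.**  Rows (or, transposed, columns) become a
  point cloud; a Vietoris–Rips filtration orders simplices by diameter, and
  Z/2 boundary-matrix reduction yields birth–death intervals
  [β, δ) with explicit creator and destroyer simplices (a triangle kills
  the youngest live 1-cycle).
* **Representative cycles.**  For an H₁ interval, the representative is the
  creator edge plus the shortest path between its endpoints in the
  1-skeleton before β.  For an H₂ interval, the complex is first converted
  to a pseudo-manifold (each triangle keeps at most two tetrahedral
  cofacets, earliest first); a minimum s–t cut on the dual flow network —
  tetrahedra as nodes plus an infinite vertex, triangles as arcs, infinite
  capacities contracted — returns a minimal-weight persistent 2-cycle
  containing the creator.
* **Cohort curation (dominant cycles).**  A cycle *Z* is *dominant* when
  one label covers at least ⌊|Vert(*Z*)|/2⌋ of its vertices.  The curated
  cohort set is the union of Vert(*Z*) over dominant cycles among the top
  *k* (default 100) per dimension, ranked by interval length δ − β.
* **Gene curation (κ cover).**  On the gene point cloud, each cycle's κ is
  the exact minimum number of annotation terms covering all of its gene
  vertices, κ = inf{ |S| : S ∩ f(g) ≠ ∅ ∀g ∈ Vert(Z) }; genes in cycles
  with κ ≤ κ_max (default 3) are kept.  "Not annotated" is an ordinary
  coverable term.
* **Evaluation.**  Repeated stratified 80/20 cross-validation with a
  decision tree and Gaussian naive Bayes, macro-averaged metrics, and a
  small 1D convolutional network (conv–sigmoid → maxpool 2 → dropout →
  two ReLU dense layers → softmax, Adam) whose input genes are sorted by
  functional annotation.

See `vignettes/topology-guided-curation.Rmd` for assumptions, parameter
semantics, numerical choices and limitations.

## Worked example

```r
library(TopoCurate)

## persistence pairing on the bundled worked filtration
pers <- computePersistence(workedFiltrationExample(), maxHomDim = 1)
finiteIntervals(pers, 1)[, c("dim", "birth_value", "death_value")]
#>   dim birth_value death_value
#> 1   1           4           9
#> 2   1           5           8
#> 3   1           6           7
```

The square-with-diagonals fixture has three 1-cycles: the edge inserted at
step 4 creates the large hole that survives until the last triangle at
step 9; the triangle at step 7 kills the youngest creator (step 6).

```r
## exact minimum annotation cover of the six-gene worked example
fx <- workedAnnotationExample()
kappaCover(fx$genes, fx$annotations)
#> CoverResult: kappa = 3 over 6 genes; cover {Cellular process, Localization, Not annotated}
```

Three terms suffice to touch every gene of the cycle, and no two do —
κ = 3 flags a moderately coherent gene set.

```r
## planted fixture: two sphere classes, 10% label-keeping outliers
sim <- plantedCohorts(plantedCohortConfig(seed = 42))
res <- curateCohorts(sim$dataset, k = 100, mode = "H1+H2", maxScale = 2.5)
res
#> CurationResult (H1+H2, k = 100): 200/200 dominant cycles, 54 cohorts selected

evaluateProbabilistic(sim$dataset, "decision_tree", reps = 10, seed = 7)@means
#> accuracy precision    recall        f1
#>   0.9750    0.9786    0.9750    0.9768
evaluateProbabilistic(curatedDataset(res), "decision_tree", reps = 10, seed = 7)@means
#> accuracy precision    recall        f1
#>        1         1         1         1
```

All 200 extracted cycles are label-dominant here (the classes are well
separated); their union contains exactly the 54 planted inliers, the 6
uncorrelated cohorts are dropped, and the decision tree's mean accuracy
over ten 80/20 splits rises from 0.975 to 1.0.

A command-line wrapper over the same functions lives in
`inst/scripts/topocurate` (subcommands `simulate`, `rips`, `persistence`,
`cycles`, `curate-cohorts`, `curate-genes`, `evaluate`, `pipeline`).

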