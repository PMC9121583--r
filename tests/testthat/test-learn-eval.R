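test_that("confusion-matrix metrics match hand computation", {
  expect_equal(computeMetrics(diag(5, 2)),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_equal(computeMetrics(matrix(c(0, 5, 5, 0), 2))[["accuracy"]], 0)
  m <- computeMetrics(matrix(c(3, 2, 1, 4), 2))  # rows true, cols predicted
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["precision"]], (3 / 5 + 4 / 5) / 2)
  expect_equal(m[["recall"]], (3 / 4 + 4 / 6) / 2, tolerance = 1e-12)
  expect_error(computeMetrics(matrix(numeric(0), 0, 0)), "empty")
  expect_error(computeMetrics(matrix(1:6, 2, 3)), "square")
})

test_that("metrics agree with per-class hand formulas across many matrices", {
  ## exhaustive over 2x2 matrices with entries 0..5
  grid <- expand.grid(a = 0:5, b = 0:5, c = 0:5, d = 0:5)
  for (i in seq_len(nrow(grid))) {
    cm <- matrix(unlist(grid[i, ]), 2, 2)
    if (sum(cm) == 0) next
    expect_equal(computeMetrics(cm), handMetrics(cm))
  }
  ## seeded sample of 3x3 matrices with entries 0..5
  set.seed(123)
  for (i in 1:2000) {
    cm <- matrix(sample(0:5, 9, replace = TRUE), 3, 3)
    if (sum(cm) == 0) next
    expect_equal(computeMetrics(cm), handMetrics(cm))
  }
})

test_that("separable classes are classified perfectly", {
  ds <- separableDataset(seed = 21L)
  mt <- evaluateProbabilistic(ds, "decision_tree", reps = 5, seed = 1)
  expect_equal(unname(mt@means["accuracy"]), 1)
  expect_equal(nrow(mt@folds), 5L)
  expect_true(all(as.matrix(mt@folds) >= 0 & as.matrix(mt@folds) <= 1))
  mtNb <- evaluateProbabilistic(ds, "naive_bayes", reps = 5, seed = 1)
  expect_gte(unname(mtNb@means["accuracy"]), 0.9)
})

test_that("shuffled labels stay inside the permutation-null band", {
  set.seed(31)
  x <- matrix(rnorm(50 * 6), 50, 6)
  rownames(x) <- sprintf("c%02d", 1:50)
  colnames(x) <- sprintf("g%d", 1:6)
  y <- sample(rep(0:1, 25))
  ds <- ExpressionDataset(x, y)
  for (model in c("decision_tree", "naive_bayes")) {
    mt <- evaluateProbabilistic(ds, model, reps = 50, seed = 2)
    expect_gte(unname(mt@means["accuracy"]), 0.35)
    expect_lte(unname(mt@means["accuracy"]), 0.65)
  }
})

test_that("identical seeds reproduce identical metric tables", {
  ds <- separableDataset(n = 30L, shift = 1, seed = 4L)
  a <- evaluateProbabilistic(ds, "decision_tree", reps = 8, seed = 99)
  b <- evaluateProbabilistic(ds, "decision_tree", reps = 8, seed = 99)
  expect_identical(a@folds, b@folds)
  c <- evaluateProbabilistic(ds, "decision_tree", reps = 8, seed = 100)
  expect_false(identical(a@folds, c@folds))
  expect_error(evaluateProbabilistic(
    ExpressionDataset(exprsValues(ds), rep(0L, 30)), "decision_tree"),
    "two phenotype classes")
})

test_that("curated-vs-full comparison runs under both leakage protocols", {
  sim <- plantedCohorts(plantedCohortConfig(nPerClass = c(20L, 20L),
                                            seed = 5L))
  cmp <- compareCuratedVsFull(sim$dataset, model = "decision_tree", reps = 3,
                              seed = 11, protocol = "within_split",
                              k = 50, mode = "H1", maxScale = 2.5)
  expect_s4_class(cmp$full, "MetricsTable")
  expect_s4_class(cmp$curated, "MetricsTable")
  cmpG <- compareCuratedVsFull(sim$dataset, model = "decision_tree", reps = 3,
                               seed = 11, protocol = "global",
                               k = 50, mode = "H1", maxScale = 2.5)
  expect_true(all(as.matrix(cmpG$curated@folds) >= 0))
})

test_that("genes sort into contiguous functional blocks, stably", {
  ann <- AnnotationMap(list(g2 = "B", g1 = "A", g3 = "A"))
  expect_equal(sortGenesByFunction(c("g2", "g1", "g3"), ann),
               c("g1", "g3", "g2"))
  ## all unannotated: input order preserved
  ann2 <- AnnotationMap(list(a = notAnnotatedTerm(), b = notAnnotatedTerm(),
                             c = notAnnotatedTerm()))
  expect_equal(sortGenesByFunction(c("b", "c", "a"), ann2), c("b", "c", "a"))
  ## seeded random map: output is a permutation with adjacent equal keys
  set.seed(6)
  genes <- sprintf("g%02d", 1:20)
  terms <- lapply(seq_along(genes), function(i)
    sample(LETTERS[1:4], sample(1:2, 1)))
  names(terms) <- genes
  ann3 <- AnnotationMap(terms)
  out <- sortGenesByFunction(sample(genes), ann3)
  expect_setequal(out, genes)
  key <- vapply(annotationTerms(ann3, out), function(t) sort(t)[1],
                character(1))
  expect_true(!is.unsorted(key))
})

test_that("CNN shapes follow the conv/pool arithmetic", {
  spec <- cnnSpec(nClasses = 2, nFilters = 32, kernelSize = 16)
  sh <- cnnShapes(spec, 100L)
  expect_equal(sh$conv, 85L)
  expect_equal(sh$pool, 42L)
  expect_equal(sh$flatten, 42L * 32L)
  expect_error(cnnShapes(spec, 10L), "kernel")
  ## actual forward pass respects the declared shapes
  params <- TopoCurate:::initCnnParams(spec, 100L)
  fw <- TopoCurate:::cnnForward(params, spec, matrix(rnorm(300), 3, 100))
  expect_equal(dim(fw$A1), c(3L * 85L, 32L))
  expect_equal(dim(fw$Fl), c(3L, 42L * 32L))
  expect_equal(dim(fw$probs), c(3L, 2L))
  ## spec validity
  expect_error(cnnSpec(nClasses = 2, denseUnits = c(64, 64)), "decreasing")
  expect_error(cnnSpec(nClasses = 2, poolSize = 3), "pool")
})

test_that("untrained CNN emits softmax rows summing to one", {
  ds <- separableDataset(n = 40L, m = 32L, seed = 13L)
  spec <- cnnSpec(nClasses = 2, kernelSize = 8, denseUnits = c(32L, 16L),
                  epochs = 0L, seed = 5L)
  fit <- trainEvalCnn(ds, spec)
  expect_equal(unname(rowSums(fit@testProbabilities)),
               rep(1, nrow(fit@testProbabilities)), tolerance = 1e-6)
})

test_that("CNN learns separable classes and records per-epoch traces", {
  set.seed(17)
  n <- 120L; L <- 64L
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * L, 0, 0.7), n, L) +
    outer(y, rep(0.8, L))
  rownames(x) <- sprintf("c%03d", 1:n)
  colnames(x) <- sprintf("g%03d", 1:L)
  ds <- ExpressionDataset(x, y)
  spec <- cnnSpec(nClasses = 2, epochs = 15L, seed = 3L)
  fit <- trainEvalCnn(ds, spec)
  expect_gt(unname(fit@testMetrics["accuracy"]), 0.9)
  expect_equal(nrow(fit@history), 2L * 15L)
  expect_true(all(c("loss", "accuracy", "f1") %in% colnames(fit@history)))
  ## functional ordering is applied when annotations are given
  ann <- AnnotationMap(stats::setNames(
    as.list(rep(c("B", "A"), each = L / 2)), colnames(x)))
  fit2 <- trainEvalCnn(ds, cnnSpec(nClasses = 2, epochs = 0L, seed = 3L),
                       ann = ann)
  expect_equal(fit2@geneOrder, c(colnames(x)[33:64], colnames(x)[1:32]))
})
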