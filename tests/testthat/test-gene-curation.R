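test_that("gene point cloud is the transposed matrix", {
  x <- matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  ds <- ExpressionDataset(x, c(0L, 1L))
  pc <- genesToPointCloud(ds)
  expect_equal(unname(pc@coords), unname(t(x)))
  expect_equal(pc@pointIds, colnames(x))
  ## involution: transposing the gene cloud recovers the rows
  expect_equal(unname(t(pc@coords)), unname(exprsValues(ds)))
  ## each gene point equals its column exactly
  set.seed(2)
  y <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:10)))
  ds2 <- ExpressionDataset(y, rep(0:1, length.out = 5))
  pc2 <- genesToPointCloud(ds2)
  for (j in 1:10) expect_equal(unname(pc2@coords[j, ]), unname(y[, j]))
})

test_that("kappa of the worked six-gene example is 3 and certified minimal", {
  fx <- workedAnnotationExample()
  cv <- kappaCover(fx$genes, fx$annotations)
  expect_equal(cv@kappa, 3L)
  ## feasibility of the returned cover
  sets <- annotationTerms(fx$annotations, fx$genes)
  expect_true(all(vapply(sets, function(s) any(s %in% cv@cover), logical(1))))
  ## exhaustive certificate: no 2-term set covers
  expect_equal(exhaustiveMinCover(sets), 3L)
  ## dropping the gene that forces Localization lowers kappa to 2
  expect_equal(kappaCover(fx$genes[-1], fx$annotations)@kappa, 2L)
  ## a shared term collapses kappa to 1
  shared <- AnnotationMap(lapply(annotationTerms(fx$annotations),
                                 function(t) c(t, "shared")))
  expect_equal(kappaCover(fx$genes, shared)@kappa, 1L)
})

test_that("kappa handles the degenerate extremes", {
  common <- AnnotationMap(list(a = c("x", "t"), b = "t", c = c("t", "z")))
  expect_equal(kappaCover(c("a", "b", "c"), common)@kappa, 1L)
  expect_equal(kappaCover(c("a", "b", "c"), common)@cover, "t")
  disjoint <- AnnotationMap(list(a = "u", b = "v", c = "w", d = "x"))
  expect_equal(kappaCover(letters[1:4], disjoint)@kappa, 4L)
  expect_error(kappaCover(character(0), common), "empty")
  expect_error(kappaCover(c("a", "zz"), common), "zz")
})

test_that("kappa matches exhaustive enumeration on 200 seeded instances", {
  for (seed in 1:200) {
    sets <- randomCoverInstance(seed)
    ann <- AnnotationMap(sets)
    cv <- kappaCover(names(sets), ann)
    expect_equal(cv@kappa, exhaustiveMinCover(sets),
                 info = paste("seed", seed))
    ## greedy is an upper bound and the cover is feasible
    covers <- vapply(sort(unique(unlist(sets))),
                     function(t) vapply(sets, function(s) t %in% s,
                                        logical(1)),
                     logical(length(sets)))
    covers <- matrix(covers, nrow = length(sets),
                     dimnames = list(names(sets),
                                     sort(unique(unlist(sets)))))
    expect_gte(length(TopoCurate:::greedySetCover(covers)), cv@kappa)
    expect_true(all(vapply(sets, function(s) any(s %in% cv@cover),
                           logical(1))))
  }
})

test_that("curateGenes selects planted co-expressed families", {
  fx <- plantedGeneFamilies(seed = 42L)
  res <- curateGenes(fx$dataset, fx$annotations, k = 3, kappaMax = 1,
                     dims = 1)
  sel <- selectedGenes(res)
  expect_gt(length(sel), 0L)
  expect_true(all(sel %in% names(fx$families)))
  recovered <- length(sel) / length(fx$families)
  expect_gte(recovered, 0.8)
  ## column order preserved in the curated dataset
  expect_equal(geneIds(curatedDataset(res)),
               geneIds(fx$dataset)[geneIds(fx$dataset) %in% sel])
})

test_that("kappaMax acts as a monotone threshold on the same cycles", {
  fx <- plantedGeneFamilies(seed = 42L)
  sel1 <- selectedGenes(curateGenes(fx$dataset, fx$annotations, k = 5,
                                    kappaMax = 1, dims = 1))
  selInf <- selectedGenes(curateGenes(fx$dataset, fx$annotations, k = 5,
                                      kappaMax = Inf, dims = 1))
  expect_true(all(sel1 %in% selInf))
  ## vacuous threshold keeps the union of all top-k cycle vertex sets
  resInf <- curateGenes(fx$dataset, fx$annotations, k = 5, kappaMax = Inf,
                        dims = 1)
  allVerts <- sort(unique(unlist(lapply(resInf@cycles, vertexSet))))
  expect_setequal(selInf, geneIds(fx$dataset)[allVerts])
  ## a threshold below every kappa empties the selection with a warning
  strict <- AnnotationMap(stats::setNames(
    lapply(seq_along(geneIds(fx$dataset)), function(i) paste0("only", i)),
    geneIds(fx$dataset)))
  expect_warning(res0 <- curateGenes(fx$dataset, strict, k = 2, kappaMax = 1,
                                     dims = 1),
                 "kappa threshold")
  expect_length(selectedGenes(res0), 0L)
})

test_that("unannotated genes are completed with the reserved term", {
  fx <- plantedGeneFamilies(seed = 3L)
  partial <- AnnotationMap(annotationTerms(fx$annotations)[1:10])
  expect_warning(ann2 <- completeAnnotations(partial,
                                             geneIds(fx$dataset)),
                 "Not annotated")
  expect_setequal(names(annotationTerms(ann2)), geneIds(fx$dataset))
  expect_equal(annotationTerms(ann2)[[geneIds(fx$dataset)[11]]],
               notAnnotatedTerm())
})
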