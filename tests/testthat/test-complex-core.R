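test_that("Rips values equal pairwise distances on simple geometries", {
  f <- ripsFiltration(rbind(c(0, 0), c(2, 0)), maxDim = 1, maxScale = 3)
  expect_equal(nSimplices(f), 3L)
  expect_equal(simplexValues(f), c(0, 0, 2))
  expect_equal(simplexDims(f), c(0L, 0L, 1L))

  tri <- ripsFiltration(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                        maxDim = 2, maxScale = 2)
  expect_equal(simplexDims(tri), c(0L, 0L, 0L, 1L, 1L, 1L, 2L))
  expect_equal(simplexValues(tri), c(0, 0, 0, 1, 1, 1, 1), tolerance = 1e-12)

  expect_error(ripsFiltration(matrix(numeric(0), 0, 2), 1, 1), "empty")
  expect_error(ripsFiltration(rbind(c(0, NA)), 1, 1), "finite")
})

test_that("every exact Rips simplex value is the brute-force diameter", {
  set.seed(7)
  coords <- matrix(rnorm(20), 10, 2)
  f <- ripsFiltration(coords, maxDim = 3, maxScale = 1.5)
  D <- as.matrix(dist(coords))
  for (i in seq_len(nSimplices(f))) {
    v <- simplexList(f)[[i]]
    expected <- if (length(v) == 1L) 0 else max(D[v, v])
    expect_equal(simplexValues(f)[i], expected, tolerance = 1e-12)
  }
  ## completeness: every vertex subset with small diameter is present
  for (s in combn(10, 3, simplify = FALSE))
    if (max(D[s, s]) <= 1.5)
      expect_false(is.na(simplexIndex(f, s)))
})

test_that("sparse Rips yields a valid sub-filtration of the exact one", {
  set.seed(3)
  coords <- matrix(rnorm(60), 30, 2)
  exact <- ripsFiltration(coords, maxDim = 2, maxScale = 1)
  sparse <- ripsFiltration(coords, maxDim = 2, maxScale = 1, sparsity = 0.9)
  expect_true(validObject(sparse))
  expect_lte(nSimplices(sparse), nSimplices(exact))
  expect_equal(sum(simplexDims(sparse) == 0L), 30L)  # all vertices kept
  exactKeys <- vapply(simplexList(exact), paste, character(1), collapse = ",")
  sparseKeys <- vapply(simplexList(sparse), paste, character(1), collapse = ",")
  expect_true(all(sparseKeys %in% exactKeys))
})

test_that("persistence pairing reproduces the worked filtration example", {
  f <- workedFiltrationExample()
  p <- computePersistence(f, maxHomDim = 1)
  h1 <- finiteIntervals(p, 1)
  expect_equal(nrow(h1), 3L)
  pairs <- cbind(h1$birth_value, h1$death_value)
  expect_true(all(apply(pairs, 1, paste, collapse = "-") %in%
                  c("4-9", "5-8", "6-7")))
  ## the triangle entering at step 7 kills the youngest creator (step 6)
  expect_equal(h1$birth_value[h1$death_value == 7], 6)
  ## the class created at step 4 survives to the last triangle
  expect_equal(h1$death_value[h1$birth_value == 4], 9)
})

test_that("single vertex yields one essential 0-interval", {
  p <- computePersistence(Filtration(list(1L), 0), maxHomDim = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$dim, 0L)
  expect_true(is.na(p$death))
  expect_equal(p$death_value, Inf)
})

test_that("malformed filtrations are rejected naming the offender", {
  expect_error(Filtration(list(c(1, 2), 1, 2), c(0, 1, 1)), "1,2")
  expect_error(Filtration(list(1, 2, c(1, 2)), c(0, 1, 0.5)),
               "non-decreasing")
})

test_that("pairing matches the naive reduction oracle on a noisy circle", {
  set.seed(11)
  th <- runif(20, 0, 2 * pi)
  coords <- cbind(cos(th), sin(th)) + matrix(rnorm(40, 0, 0.1), 20, 2)
  f <- ripsFiltration(coords, maxDim = 2, maxScale = 1.2)
  p <- computePersistence(f, maxHomDim = 1)
  oracle <- naiveReduction(f)
  got <- p[!is.na(p$death), c("dim", "birth", "death")]
  want <- oracle$pairs[oracle$pairs$dim <= 1L, ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[order(got$birth), ], want[order(want$birth), ],
               ignore_attr = TRUE)
  gotEss <- p[is.na(p$death), c("dim", "birth")]
  wantEss <- oracle$essential[oracle$essential$dim <= 1L, , drop = FALSE]
  expect_equal(gotEss$birth[order(gotEss$birth)],
               wantEss$birth[order(wantEss$birth)])
})

test_that("interval monotonicity and pairing conservation hold on random complexes", {
  for (seed in 1:10) {
    f <- randomRipsFiltration(seed)
    p <- computePersistence(f, maxHomDim = 2)
    fin <- p[!is.na(p$death), ]
    expect_true(all(fin$birth_value <= fin$death_value))
    expect_true(all(fin$birth < fin$death))
    oracle <- naiveReduction(f)
    for (d in 0:2) {
      expect_equal(sum(fin$dim == d) + sum(p$dim == d & is.na(p$death)),
                   sum(oracle$pairs$dim == d) +
                     sum(oracle$essential$dim == d))
    }
  }
})

test_that("finiteIntervals filters by dimension and preserves order", {
  p <- computePersistence(workedFiltrationExample(), maxHomDim = 1)
  h1 <- finiteIntervals(p, 1)
  expect_equal(nrow(h1), 3L)
  expect_true(all(h1$dim == 1L))
  expect_true(!is.unsorted(h1$birth))
  h0 <- finiteIntervals(p, 0)
  expect_true(all(h0$dim == 0L))
  empty <- finiteIntervals(p[0, ], 1)
  expect_equal(nrow(empty), 0L)
})

test_that("topKByLength matches a full sort oracle and breaks ties by birth", {
  set.seed(5)
  iv <- data.frame(dim = 1L, birth = sample(1000, 50), death = 0L,
                   birth_value = runif(50), creator = "x", destroyer = "y")
  iv$death <- iv$birth + 1L
  iv$death_value <- iv$birth_value + sample(c(1, 3, 5), 50, replace = TRUE)
  top <- topKByLength(iv, 10)
  len <- iv$death_value - iv$birth_value
  oracle <- iv[order(-len, iv$birth), ][1:10, ]
  expect_equal(top, oracle, ignore_attr = TRUE)
  expect_equal(nrow(topKByLength(iv, 0)), 0L)
  expect_equal(nrow(topKByLength(iv, 500)), 50L)
  expect_error(topKByLength(iv, -1), ">= 0")
  lv <- c(5, 1, 3)
  iv3 <- data.frame(dim = 1L, birth = 1:3, death = 4:6, birth_value = 0,
                    death_value = lv, creator = "x", destroyer = "y")
  expect_equal(topKByLength(iv3, 2)$death_value, c(5, 3))
})

test_that("filtration text round-trips through write and read", {
  f <- workedFiltrationExample()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFiltration(f, path)
  g <- readFiltration(path)
  expect_equal(simplexList(g), simplexList(f))
  expect_equal(simplexValues(g), simplexValues(f))
  p <- computePersistence(g, 1)
  expect_equal(nrow(finiteIntervals(p, 1)), 3L)
})
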