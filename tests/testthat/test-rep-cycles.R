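test_that("H1 representative is the unique shortest cycle on toy complexes", {
  ## triangle with edge ca inserted last: the only cycle
  tri <- Filtration(list(1, 2, 3, c(1, 2), c(2, 3), c(1, 3), c(1, 2, 3)),
                    c(0, 0, 0, 1, 1, 2, 3))
  p <- computePersistence(tri, 1)
  cy <- h1Cycle(tri, finiteIntervals(p, 1), "hop")
  expect_setequal(vapply(cycleSimplices(cy), paste, character(1),
                         collapse = ","),
                  c("1,2", "2,3", "1,3"))

  ## square closed by edge da: path a-b-c-d plus da
  sq <- squareFiltration()
  p <- computePersistence(sq, 1)
  iv <- finiteIntervals(p, 1)
  cy <- h1Cycle(sq, iv[iv$birth == 7, ], "hop")
  expect_setequal(vapply(cycleSimplices(cy), paste, character(1),
                         collapse = ","),
                  c("1,2", "2,3", "3,4", "1,4"))
  expect_equal(vertexSet(cy), 1:4)
  expect_true(validObject(cy))
})

test_that("H1 cycle on a planted noisy circle stays near the unit circle", {
  noise <- 0.05
  ds <- noisyCircleDataset(n = 30L, noiseSd = noise, seed = 42L)
  coords <- exprsValues(ds)
  f <- ripsFiltration(coords, maxDim = 2, maxScale = enclosingRadius(coords))
  p <- computePersistence(f, 1)
  top <- topKByLength(finiteIntervals(p, 1), 1)
  cy <- h1Cycle(f, top)
  radii <- sqrt(rowSums(coords[vertexSet(cy), ]^2))
  expect_true(all(abs(radii - 1) <= 3 * noise))
  ## member edges never postdate the birth index
  idx <- vapply(cycleSimplices(cy), function(e) simplexIndex(f, e), integer(1))
  expect_true(all(idx <= cy@birth))
})

test_that("pseudo-manifoldization keeps the two earliest cofacets per triangle", {
  ## complex already pseudo-manifold: identity up to the flag
  f <- hollowTetraConed()
  pm <- pseudoManifoldize(f)
  expect_equal(simplexList(pm), simplexList(f))
  expect_true(isPseudoManifold(pm))

  ## one triangle with three cofacet tetrahedra at values 1 < 2 < 3
  tris <- list(c(1, 2, 3))
  cof <- list(c(1, 2, 3, 4), c(1, 2, 3, 5), c(1, 2, 3, 6))
  below <- c(as.list(1:6),
             combn(4, 2, simplify = FALSE),
             lapply(1:3, function(i) c(i, 5)), lapply(1:3, function(i) c(i, 6)),
             tris,
             lapply(combn(3, 2, simplify = FALSE), function(e) c(e, 4)),
             lapply(combn(3, 2, simplify = FALSE), function(e) c(e, 5)),
             lapply(combn(3, 2, simplify = FALSE), function(e) c(e, 6)))
  f3 <- Filtration(c(below, cof), c(rep(0, length(below)), 1, 2, 3))
  pm3 <- pseudoManifoldize(f3)
  keys <- vapply(simplexList(pm3), paste, character(1), collapse = ",")
  expect_true("1,2,3,4" %in% keys)
  expect_true("1,2,3,5" %in% keys)
  expect_false("1,2,3,6" %in% keys)
})

test_that("pseudo-manifold invariant holds on seeded random 3-complexes", {
  for (seed in 1:5) {
    f <- randomRipsFiltration(seed + 100, maxSimplices = 400L)
    pm <- pseudoManifoldize(f)
    simp <- simplexList(pm)
    triKeys <- vapply(simp[simplexDims(pm) == 2L], paste, character(1),
                      collapse = ",")
    counts <- stats::setNames(integer(length(triKeys)), triKeys)
    for (q in simp[simplexDims(pm) == 3L]) {
      fk <- vapply(seq_along(q), function(i) paste(q[-i], collapse = ","),
                   character(1))
      counts[fk] <- counts[fk] + 1L
    }
    expect_true(all(counts <= 2L))
    ## simplices of dim <= 2 all survive
    expect_equal(sum(simplexDims(pm) <= 2L), sum(simplexDims(f) <= 2L))
  }
})

test_that("H2 cycle of the coned hollow tetrahedron is its boundary", {
  f <- pseudoManifoldize(hollowTetraConed())
  p <- computePersistence(f, 2)
  iv <- topKByLength(finiteIntervals(p, 2), 1)
  cy <- h2Cycle(f, iv, "unit")
  expect_setequal(vapply(cycleSimplices(cy), paste, character(1),
                         collapse = ","),
                  c("1,2,3", "1,2,4", "1,3,4", "2,3,4"))
  expect_error(h2Cycle(hollowTetraConed(), iv), "pseudoManifoldize")
})

test_that("H2 min-cut equals exhaustive minimum 2-cycle on the octahedron", {
  f <- pseudoManifoldize(octahedronFilled())
  p <- computePersistence(f, 2)
  iv <- topKByLength(finiteIntervals(p, 2), 1)
  cy <- h2Cycle(f, iv, "unit")
  expect_equal(length(cycleSimplices(cy)), 8L)
  oracle <- enumerateMin2Cycle(f, iv$birth)
  expect_equal(length(cycleSimplices(cy)), oracle$weight)
})

test_that("H2 min-cut finds a strictly smaller cycle than the outer sphere", {
  f <- bipyramidFilled()
  expect_true(validObject(f))
  pm <- pseudoManifoldize(f)
  p <- computePersistence(pm, 2)
  iv <- finiteIntervals(p, 2)
  for (r in seq_len(nrow(iv))) {
    cy <- h2Cycle(pm, iv[r, ], "unit")
    oracle <- enumerateMin2Cycle(pm, iv[r, ]$birth)
    expect_equal(length(cycleSimplices(cy)), oracle$weight)
    expect_equal(length(cycleSimplices(cy)), 4L)  # one tetra boundary
  }
})

test_that("H2 cut weight equals an independent augmenting-path max flow", {
  fixtures <- list(pseudoManifoldize(hollowTetraConed()),
                   pseudoManifoldize(octahedronFilled()),
                   pseudoManifoldize(octahedronFilled(jitter = 0.05,
                                                      seed = 2L)),
                   pseudoManifoldize(bipyramidFilled()))
  for (f in fixtures) {
    p <- computePersistence(f, 2)
    iv <- finiteIntervals(p, 2)
    for (r in seq_len(nrow(iv))) {
      for (ws in c("unit", "filtration_value")) {
        cy <- h2Cycle(f, iv[r, ], ws)
        net <- TopoCurate:::h2DualNetwork(f, iv[r, ], ws)
        n <- net$nTetra + 1L
        ## emulate the contracted sink set with infinite arcs to the sink
        from <- c(net$from, rep(net$infNode, length(net$sinks) - 1L))
        to <- c(net$to, setdiff(net$sinks, net$infNode))
        cap <- c(net$capacity, rep(Inf, length(net$sinks) - 1L))
        flow <- edmondsKarpMaxFlow(n, from, to, cap, net$source, net$infNode)
        expect_equal(attr(cy, "cutWeight"), flow, tolerance = 1e-9)
        expect_equal(attr(cy, "flowValue"), flow, tolerance = 1e-9)
      }
    }
  }
})

test_that("H2 cycle on a planted noisy sphere stays near the unit sphere", {
  noise <- 0.05
  ds <- noisySphereDataset(n = 40L, noiseSd = noise, seed = 42L)
  coords <- exprsValues(ds)
  f <- pseudoManifoldize(ripsFiltration(coords, maxDim = 3, maxScale = 1.6))
  p <- computePersistence(f, 2)
  top <- topKByLength(finiteIntervals(p, 2), 1)
  cy <- h2Cycle(f, top)
  radii <- sqrt(rowSums(coords[vertexSet(cy), ]^2))
  expect_true(all(abs(radii - 1) <= 3 * noise))
  expect_true(validObject(cy))
})

test_that("cyclesForIntervals maps intervals in order and flags failures", {
  f <- workedFiltrationExample()
  p <- computePersistence(f, 1)
  iv <- finiteIntervals(p, 1)
  got <- cyclesForIntervals(f, iv, 1, weightScheme = "hop")
  expect_length(got$cycles, 3L)
  expect_equal(nrow(got$failures), 0L)
  for (cy in got$cycles) expect_true(validObject(cy))
  expect_equal(vapply(got$cycles, function(cy) cy@birth, integer(1)),
               iv$birth)

  empty <- cyclesForIntervals(f, iv[0, ], 1)
  expect_length(empty$cycles, 0L)

  ## a corrupted interval (creator not an edge) is flagged, others returned
  bad <- iv
  bad$birth[2] <- 0L
  expect_warning(got2 <- cyclesForIntervals(f, bad, 1, weightScheme = "hop"),
                 "failed")
  expect_length(got2$cycles, 2L)
  expect_equal(got2$failures$row, 2L)
})

test_that("cycle JSON export records intervals and vertex sets", {
  f <- workedFiltrationExample()
  p <- computePersistence(f, 1)
  got <- cyclesForIntervals(f, finiteIntervals(p, 1), 1,
                            weightScheme = "hop")
  path <- withr::local_tempfile(fileext = ".json")
  writeCycles(got$cycles, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back), 3L)
  expect_setequal(back$birth_value, c(4, 5, 6))
})
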