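## Small complexes and generators used across test files; all built in code.

## square a-b-c-d: tree edges first, closing edge, diagonal, two triangles
squareFiltration <- function() {
  Filtration(list(1, 2, 3, 4, c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(1, 3),
                  c(1, 2, 3), c(1, 3, 4)),
             c(0, 0, 0, 0, 1, 1, 1, 2, 3, 4, 4))
}

## hollow tetrahedron on vertices 1..4 coned off by vertex 5
hollowTetraConed <- function() {
  v <- as.list(1:5)
  bedges <- combn(4, 2, simplify = FALSE)
  btris <- combn(4, 3, simplify = FALSE)
  cedges <- lapply(1:4, function(i) c(i, 5))
  ctris <- lapply(combn(4, 2, simplify = FALSE), function(e) c(e, 5))
  tets <- lapply(combn(4, 3, simplify = FALSE), function(t) c(t, 5))
  Filtration(c(v, bedges, btris, cedges, ctris, tets),
             c(rep(0, 5), rep(1, 6), rep(2, 4), rep(3, 4), rep(4, 6),
               rep(5, 4)))
}

## octahedron boundary, interior filled after birth through a center vertex;
## optional coordinate jitter keeps the combinatorics but perturbs geometry
octahedronFilled <- function(jitter = 0, seed = 1L) {
  set.seed(seed)
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  pts <- pts + matrix(runif(18, -jitter, jitter), 6, 3)
  d <- function(e) sqrt(sum((pts[e[1], ] - pts[e[2], ])^2))
  edges <- Filter(function(e) d(e) < 1.9, combn(6, 2, simplify = FALSE))
  faces <- Filter(function(t) all(combn(t, 2, d) < 1.9),
                  combn(6, 3, simplify = FALSE))
  ctrE <- lapply(1:6, function(i) c(i, 7))
  ctrT <- lapply(edges, function(e) c(e, 7))
  tets <- lapply(faces, function(t) c(t, 7))
  Filtration(c(as.list(1:6), edges, faces, list(7), ctrE, ctrT, tets),
             c(rep(0, 6), rep(1, length(edges)), rep(2, length(faces)), 3,
               rep(3, 6), rep(4, length(ctrT)), rep(5, length(tets))))
}

## triangular bipyramid: 2-sphere of six triangles plus the equatorial
## triangle, filled by its two tetrahedra; the minimal 2-cycle through a
## boundary triangle is one tetrahedron boundary (4 triangles), strictly
## smaller than the 6-triangle outer sphere
bipyramidFilled <- function() {
  eq <- list(c(1, 2), c(1, 3), c(2, 3))
  up <- lapply(1:3, function(i) c(i, 4))
  dn <- lapply(1:3, function(i) c(i, 5))
  eqT <- list(c(1, 2, 3))
  upT <- list(c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  dnT <- list(c(1, 2, 5), c(1, 3, 5), c(2, 3, 5))
  tets <- list(c(1, 2, 3, 4), c(1, 2, 3, 5))
  Filtration(c(as.list(1:5), eq, up, dn, eqT, upT, dnT, tets),
             c(rep(0, 5), rep(1, 3), rep(2, 3), rep(3, 3), 4,
               rep(5, 3), rep(6, 3), rep(7, 2)))
}

## seeded random Rips filtration capped at `maxSimplices`
randomRipsFiltration <- function(seed, maxSimplices = 200L) {
  set.seed(seed)
  n <- sample(6:10, 1L)
  dd <- sample(2:3, 1L)
  maxDim <- sample(2:3, 1L)
  coords <- matrix(runif(n * dd), n, dd)
  scale <- stats::quantile(dist(coords), 0.7)
  repeat {
    f <- ripsFiltration(coords, maxDim = maxDim, maxScale = scale)
    if (nSimplices(f) <= maxSimplices) return(f)
    scale <- scale * 0.8
  }
}

## seeded random small annotation instance for the cover oracle
randomCoverInstance <- function(seed) {
  set.seed(seed)
  nGenes <- sample(2:8, 1L)
  vocab <- paste0("t", seq_len(sample(3:10, 1L)))
  sets <- lapply(seq_len(nGenes), function(i)
    sort(sample(vocab, sample(1:3, 1L))))
  names(sets) <- paste0("g", seq_len(nGenes))
  sets
}

## single-class planted circle / sphere clouds for geometry recovery
noisyCircleDataset <- function(n = 30L, noiseSd = 0.05, seed = 1L) {
  cfg <- plantedCohortConfig(nPerClass = n, m = 2L,
                             structures = list(list(type = "circle",
                                                    center = 0, radius = 1)),
                             noiseSd = noiseSd, outlierFraction = 0,
                             seed = seed)
  plantedCohorts(cfg)$dataset
}

noisySphereDataset <- function(n = 40L, noiseSd = 0.05, seed = 1L) {
  cfg <- plantedCohortConfig(nPerClass = n, m = 3L,
                             structures = list(list(type = "sphere",
                                                    center = 0, radius = 1)),
                             noiseSd = noiseSd, outlierFraction = 0,
                             seed = seed)
  plantedCohorts(cfg)$dataset
}

## two separable gaussian classes as an ExpressionDataset
separableDataset <- function(n = 60L, m = 6L, shift = 4, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  y <- rep(0:1, length.out = n)
  x[, 1L] <- x[, 1L] + shift * y
  rownames(x) <- sprintf("c%03d", seq_len(n))
  colnames(x) <- sprintf("g%02d", seq_len(m))
  ExpressionDataset(x, y)
}
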