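## Deterministic generators for all test inputs: the two worked examples
## encoded as fixtures, planted-topology labeled cohorts, and annotation maps
## with planted gene families.

#' Worked filtration example: square with both diagonals
#'
#' Ten filtration steps over thirteen simplices: four vertices with a
#' spanning tree of edges (values 0..3), the square-closing edge at value 4,
#' the two diagonals at values 5 and 6, and three triangles at values 7, 8
#' and 9.  Persistence pairing yields the three finite 1-dimensional
#' intervals (6,7), (5,8) and (4,9) on the value scale.
#'
#' @return An abstract [Filtration-class] whose values carry the step
#'   numbering.
#' @export
workedFiltrationExample <- function() {
  a <- 1L; b <- 2L; c <- 3L; d <- 4L
  simplices <- list(a, b, c(a, b),
                    c, c(b, c),
                    d, c(c, d),
                    c(a, d), c(a, c), c(b, d),
                    c(a, b, d), c(a, b, c), c(a, c, d))
  values <- c(0, 1, 1, 2, 2, 3, 3, 4, 5, 6, 7, 8, 9)
  Filtration(simplices, values)
}

#' Worked annotation example: six genes, kappa = 3
#'
#' Six genes with term sets {Localization}, {Not annotated},
#' {Metabolic process, Cellular process},
#' {Metabolic process, Cellular process, Biological regulation},
#' {Metabolic process, Cellular process, Localization}, {Not annotated}; the
#' two spellings of the unannotated term are normalised to one.
#'
#' @return A list with `genes` (character) and `annotations`
#'   ([AnnotationMap-class]).
#' @export
workedAnnotationExample <- function() {
  na <- notAnnotatedTerm()
  terms <- list(
    gene1 = "Localization",
    gene2 = na,
    gene3 = c("Metabolic process", "Cellular process"),
    gene4 = c("Metabolic process", "Cellular process", "Biological regulation"),
    gene5 = c("Metabolic process", "Cellular process", "Localization"),
    gene6 = na)
  list(genes = names(terms), annotations = AnnotationMap(terms))
}

#' Construct a PlantedCohortConfig
#'
#' Defaults encode the standard planted-structure study condition: two
#' classes of 30 cohorts sampled from unit 2-spheres centred at -3 and +3 on
#' the first of 8 synthetic gene axes, isotropic Gaussian noise of sd 0.05,
#' and 10 percent of cohorts replaced by label-keeping uniform outliers
#' (modeling uncorrelated measurements).
#'
#' @param nPerClass integer counts per class.
#' @param m ambient dimension.
#' @param structures list of per-class `list(type, center, radius)`.
#' @param noiseSd,outlierFraction,seed generator settings.
#' @return A [PlantedCohortConfig-class].
#' @export
plantedCohortConfig <- function(nPerClass = c(30L, 30L), m = 8L,
                                structures = list(
                                  list(type = "sphere", center = -3, radius = 1),
                                  list(type = "sphere", center = 3, radius = 1)),
                                noiseSd = 0.05, outlierFraction = 0.1,
                                seed = 1L) {
  new("PlantedCohortConfig", nPerClass = as.integer(nPerClass),
      m = as.integer(m), structures = structures, noiseSd = noiseSd,
      outlierFraction = outlierFraction, seed = as.integer(seed))
}

sampleStructure <- function(type, n, radius) {
  switch(type,
    sphere = {
      u <- matrix(rnorm(3L * n), n, 3L)
      u * (radius / sqrt(rowSums(u^2)))
    },
    circle = {
      th <- runif(n, 0, 2 * pi)
      cbind(radius * cos(th), radius * sin(th))
    },
    torus = {
      th <- runif(n, 0, 2 * pi); ph <- runif(n, 0, 2 * pi)
      r <- 0.4 * radius
      cbind((radius + r * cos(ph)) * cos(th),
            (radius + r * cos(ph)) * sin(th), r * sin(ph))
    },
    gaussian_blob = matrix(rnorm(3L * n, sd = radius), n, 3L))
}

#' Generate a labeled expression-like matrix with planted topology
#'
#' Each class is sampled from its geometric structure embedded in the leading
#' coordinates of an m-dimensional space plus isotropic noise.  The noise is
#' uniform with standard deviation `noiseSd` (support `+-noiseSd*sqrt(3)`), so
#' every clean cohort lies within `3*noiseSd` of its planted surface by
#' construction, which makes planted-geometry recovery checks deterministic
#' rather than merely high-probability.  A seeded fraction of cohorts is then
#' replaced by draws from a broad uniform box while keeping their class
#' label, emulating cohorts whose measurements are uncorrelated with their
#' phenotype.  Fully deterministic given the seed.
#'
#' @param cfg a [PlantedCohortConfig-class].
#' @return A list with `dataset` ([ExpressionDataset-class]) and `truth`
#'   (data.frame with cohortId, label, outlier flag).
#' @export
plantedCohorts <- function(cfg) {
  stopIfNot(isTRUE(validObject(cfg, test = TRUE)), "invalid config")
  set.seed(cfg@seed)
  n <- sum(cfg@nPerClass)
  m <- cfg@m
  a <- cfg@noiseSd * sqrt(3)     # uniform noise with sd = noiseSd
  coords <- matrix(runif(n * m, -a, a), n, m)
  labels <- integer(n)
  at <- 0L
  for (ci in seq_along(cfg@nPerClass)) {
    nc <- cfg@nPerClass[ci]
    s <- cfg@structures[[ci]]
    pts <- sampleStructure(s$type, nc, s$radius %||% 1)
    center <- rep(s$center %||% 0, length.out = m)
    rows <- at + seq_len(nc)
    coords[rows, ] <- sweep(coords[rows, , drop = FALSE], 2L, center, "+")
    coords[rows, seq_len(ncol(pts))] <-
      coords[rows, seq_len(ncol(pts)), drop = FALSE] + pts
    labels[rows] <- ci - 1L
    at <- at + nc
  }
  outlier <- rep(FALSE, n)
  nOut <- floor(cfg@outlierFraction * n)
  if (nOut > 0L) {
    idx <- sample(n, nOut)
    lim <- 2 * max(abs(coords))
    coords[idx, ] <- matrix(runif(nOut * m, -lim, lim), nOut, m)
    outlier[idx] <- TRUE
  }
  ids <- sprintf("c%03d", seq_len(n))
  rownames(coords) <- ids
  colnames(coords) <- sprintf("g%02d", seq_len(m))
  list(dataset = ExpressionDataset(coords, labels),
       truth = data.frame(cohortId = ids, label = labels, outlier = outlier,
                          stringsAsFactors = FALSE))
}

#' Annotation map with planted gene families
#'
#' Genes are partitioned into seeded families; family members share the term
#' `family_<i>` plus optional extra terms drawn from `vocab`; leftover genes
#' carry only the reserved unannotated term.
#'
#' @param geneIds character vector.
#' @param nFamilies,familySize family layout; must fit in `length(geneIds)`.
#' @param vocab character vector of extra terms (may be empty).
#' @param extraProb probability that a family gene receives one extra term.
#' @param seed integer.
#' @return A list with `annotations` ([AnnotationMap-class]) and `families`
#'   (named character: gene -> family term, leftover genes absent).
#' @export
plantedAnnotations <- function(geneIds, nFamilies, familySize,
                               vocab = character(0), extraProb = 0,
                               seed = 1L) {
  stopIfNot(nFamilies * familySize <= length(geneIds),
            "families do not fit within the gene count")
  set.seed(as.integer(seed))
  picked <- sample(geneIds, nFamilies * familySize)
  fam <- rep(sprintf("family_%d", seq_len(nFamilies)), each = familySize)
  names(fam) <- picked
  terms <- lapply(geneIds, function(g) {
    if (g %in% picked) {
      t <- fam[[g]]
      if (length(vocab) && extraProb > 0 && runif(1) < extraProb)
        t <- c(t, sample(vocab, 1L))
      t
    } else notAnnotatedTerm()
  })
  names(terms) <- geneIds
  list(annotations = AnnotationMap(terms), families = fam)
}

#' Expression dataset with planted co-expressed gene families
#'
#' Builds a gene point cloud directly: each family lies on a planted circle
#' in its own pair of cohort coordinates with a family-specific offset, so
#' the transposed matrix carries one long 1-cycle per family; noise genes are
#' scattered uniformly.  Family genes share a family annotation term, noise
#' genes are unannotated.
#'
#' @param nFamilies number of families (default 3).
#' @param genesPerFamily genes per family (default 12).
#' @param nNoise scattered unannotated genes (default 5).
#' @param nCohorts ambient dimension of the gene cloud (default 12).
#' @param noiseSd coordinate jitter (default 0.05).
#' @param seed integer.
#' @return A list with `dataset`, `annotations` and `families` (named
#'   character, as in [plantedAnnotations()]).
#' @export
plantedGeneFamilies <- function(nFamilies = 3L, genesPerFamily = 12L,
                                nNoise = 5L, nCohorts = 12L, noiseSd = 0.05,
                                seed = 1L) {
  stopIfNot(2L * nFamilies <= nCohorts,
            "need two cohort coordinates per family")
  set.seed(as.integer(seed))
  m <- nFamilies * genesPerFamily + nNoise
  coords <- matrix(rnorm(m * nCohorts, sd = noiseSd), m, nCohorts)
  geneIds <- sprintf("g%03d", seq_len(m))
  fam <- character(0)
  for (f in seq_len(nFamilies)) {
    rows <- (f - 1L) * genesPerFamily + seq_len(genesPerFamily)
    th <- 2 * pi * (seq_len(genesPerFamily) - 1L) / genesPerFamily +
      rnorm(genesPerFamily, sd = 0.05)
    cols <- c(2L * f - 1L, 2L * f)
    coords[rows, cols[1L]] <- coords[rows, cols[1L]] + cos(th) + 8 * f
    coords[rows, cols[2L]] <- coords[rows, cols[2L]] + sin(th)
    fam <- c(fam, stats::setNames(rep(sprintf("family_%d", f), genesPerFamily),
                                  geneIds[rows]))
  }
  if (nNoise > 0L) {
    rows <- nFamilies * genesPerFamily + seq_len(nNoise)
    coords[rows, ] <- matrix(runif(nNoise * nCohorts, -30, 30), nNoise,
                             nCohorts)
  }
  terms <- lapply(geneIds, function(g)
    if (g %in% names(fam)) fam[[g]] else notAnnotatedTerm())
  names(terms) <- geneIds
  values <- t(coords)                      # cohorts x genes
  rownames(values) <- sprintf("c%02d", seq_len(nCohorts))
  colnames(values) <- geneIds
  labels <- rep_len(c(0L, 1L), nCohorts)   # labels unused by gene curation
  list(dataset = ExpressionDataset(values, labels),
       annotations = AnnotationMap(terms), families = fam)
}
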