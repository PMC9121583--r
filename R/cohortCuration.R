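## Dominant-cycle cohort curation: cohorts-as-points, top-k cycles by
## interval length, dominance by phenotype label, union of dominant cycle
## vertex sets.

applyScaling <- function(values, scaling) {
  switch(scaling,
    none = values,
    zscore = {
      mu <- colMeans(values)
      sdv <- apply(values, 2L, sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1   # constant columns become zero
      sweep(sweep(values, 2L, mu, "-"), 2L, sdv, "/")
    },
    log2 = {
      if (any(values <= 0))
        stop("log2 scaling requires strictly positive values", call. = FALSE)
      log2(values)
    },
    stop("unknown scaling: ", scaling, call. = FALSE))
}

#' Cohort point cloud of an expression dataset
#'
#' One point per cohort; coordinates are the (optionally transformed) gene
#' expression values, so n cohorts yield n points in m dimensions.
#'
#' @param ds an [ExpressionDataset-class].
#' @param scaling `"none"` (default), `"zscore"` (per-gene standardisation;
#'   constant genes map to zero) or `"log2"`.
#' @return A labeled [PointCloud-class].
#' @export
cohortsToPointCloud <- function(ds, scaling = c("none", "zscore", "log2")) {
  scaling <- match.arg(scaling)
  v <- applyScaling(exprsValues(ds), scaling)
  PointCloud(v, pointIds = cohortIds(ds), labels = unname(phenotype(ds)))
}

#' Label dominance of one representative cycle
#'
#' A cycle Z is dominant when some label covers at least
#' `floor(|Vert(Z)|/2)` of its vertices.  Among labels reaching the maximal
#' count, the smallest label value dominates (deterministic tie rule).
#'
#' @param cycle a [RepCycle-class] whose vertices index `labels`.
#' @param labels integer labels in point order (position i labels vertex i).
#' @return A [DominanceReport-class].
#' @export
dominanceReport <- function(cycle, labels) {
  vs <- vertexSet(cycle)
  lv <- labels[vs]
  if (anyNA(lv))
    stop("unlabeled cycle vertex: ",
         paste(vs[is.na(lv)], collapse = ", "), call. = FALSE)
  counts <- table(lv)
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  nv <- length(vs)
  mx <- max(cnt)
  dominant <- mx >= floor(nv / 2)
  winner <- if (dominant)
    min(as.integer(names(cnt)[cnt == mx])) else NA_integer_
  new("DominanceReport", cycle = cycle, labelCounts = cnt,
      dominant = dominant, dominatingLabel = winner,
      dominanceRatio = mx / nv)
}

normalizeMode <- function(mode) {
  m <- toupper(gsub("\\s", "", mode))
  stopIfNot(m %in% c("H1", "H2", "H1+H2"), "mode must be H1, H2 or H1+H2")
  m
}

## shared driver: filtration + persistence + top-k cycles per dimension
topCyclesForCloud <- function(pc, dims, k, maxScale = NULL, sparsity = NULL,
                              h1Weights = "euclidean",
                              h2Weights = "filtration_value") {
  maxDim <- max(dims) + 1L
  if (is.null(maxScale)) maxScale <- enclosingRadius(pc@coords)
  if (maxScale <= 0) maxScale <- .Machine$double.eps
  filt <- ripsFiltration(pc@coords, maxDim = maxDim, maxScale = maxScale,
                         sparsity = sparsity)
  if (2L %in% dims) filt <- pseudoManifoldize(filt)
  pers <- computePersistence(filt, maxHomDim = max(dims))
  cycles <- list()
  for (d in dims) {
    fin <- finiteIntervals(pers, d)
    top <- topKByLength(fin, k)
    if (nrow(top) == 0L) next
    got <- cyclesForIntervals(filt, top, d,
                              weightScheme = if (d == 1L) h1Weights
                                             else h2Weights)
    cycles <- c(cycles, got$cycles)
  }
  list(filtration = filt, persistence = pers, cycles = cycles)
}

#' Curate cohorts through dominant cycles
#'
#' Converts the dataset to a cohort point cloud, builds a Rips filtration
#' (pseudo-manifoldized when H2 cycles are requested), extracts the top `k`
#' cycles per requested homology dimension by interval length, and selects
#' the union of the vertex sets of the dominant cycles as the curated cohort
#' subset; the curated dataset preserves the original row order.
#'
#' @param ds an [ExpressionDataset-class].
#' @param k cycles considered per homology dimension (default 100).
#' @param mode `"H1+H2"` (default), `"H1"` or `"H2"`.
#' @param scaling point-cloud scaling, see [cohortsToPointCloud()].
#' @param maxScale maximal Rips scale; defaults to the enclosing radius.
#' @param sparsity NULL (exact Rips) or a sparse-Rips ratio in (0,1].
#' @param h1Weights,h2Weights weight schemes for the cycle extractors.
#' @return A [CurationResult-class].
#' @export
curateCohorts <- function(ds, k = 100L, mode = c("H1+H2", "H1", "H2"),
                          scaling = "none", maxScale = NULL, sparsity = NULL,
                          h1Weights = "euclidean",
                          h2Weights = "filtration_value") {
  mode <- normalizeMode(if (length(mode) > 1L) mode[1L] else mode)
  k <- as.integer(k)
  stopIfNot(k >= 0L, "k must be >= 0")
  dims <- switch(mode, "H1" = 1L, "H2" = 2L, "H1+H2" = c(1L, 2L))
  pc <- cohortsToPointCloud(ds, scaling)

  reports <- list(); cycles <- list(); selectedIdx <- integer(0)
  if (k > 0L) {
    run <- topCyclesForCloud(pc, dims, k, maxScale = maxScale,
                             sparsity = sparsity, h1Weights = h1Weights,
                             h2Weights = h2Weights)
    cycles <- run$cycles
    if (length(cycles) == 0L)
      warning("no finite intervals in the requested dimensions; ",
              "selection is empty", call. = FALSE)
    reports <- lapply(cycles, dominanceReport, labels = pc@labels)
    dom <- vapply(reports, function(r) r@dominant, logical(1))
    selectedIdx <- sort(unique(unlist(lapply(cycles[dom], vertexSet))))
  }
  selected <- pc@pointIds[selectedIdx]
  curated <- if (length(selected)) selectCohorts(ds, selected) else NULL
  new("CurationResult", selectedCohorts = selected, mode = mode, k = k,
      reports = reports, cycles = cycles, curated = curated)
}
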