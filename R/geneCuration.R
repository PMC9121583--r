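## kappa-based gene curation: genes-as-points on the transposed matrix, top
## cycles, exact minimum set cover over annotation terms, selection of
## low-kappa cycle vertices.

#' Gene point cloud of an expression dataset
#'
#' One point per gene; coordinates are its expression across cohorts, so m
#' genes yield m points in n dimensions (the transposed matrix).
#'
#' @param ds an [ExpressionDataset-class].
#' @param scaling applied to the transposed coordinate columns, see
#'   [cohortsToPointCloud()].
#' @return An unlabeled [PointCloud-class].
#' @export
genesToPointCloud <- function(ds, scaling = c("none", "zscore", "log2")) {
  scaling <- match.arg(scaling)
  v <- applyScaling(t(exprsValues(ds)), scaling)
  PointCloud(v, pointIds = geneIds(ds))
}

greedySetCover <- function(covers) {
  uncovered <- rep(TRUE, nrow(covers))
  chosen <- character(0)
  while (any(uncovered)) {
    gain <- colSums(covers[uncovered, , drop = FALSE])
    best <- which.max(gain)        # first maximum: lexicographic tie-break
    if (gain[best] == 0L) stop("uncoverable gene", call. = FALSE)
    chosen <- c(chosen, colnames(covers)[best])
    uncovered <- uncovered & !covers[, best]
  }
  chosen
}

## first (lexicographic) cover of exactly `size` terms, or NULL;
## terms adding no new coverage at their position are skipped, which cannot
## lose a minimum-size cover
coverSearchRec <- function(covers, size, start, uncovered) {
  nT <- ncol(covers)
  if (!any(uncovered)) return(integer(0))
  if (size == 0L || start > nT) return(NULL)
  for (t in start:nT) {
    if (nT - t + 1L < size) return(NULL)
    newly <- uncovered & covers[, t]
    if (!any(newly)) next
    rest <- coverSearchRec(covers, size - 1L, t + 1L, uncovered & !newly)
    if (!is.null(rest)) return(c(t, rest))
  }
  NULL
}

#' Exact minimum annotation cover (kappa) of a gene set
#'
#' kappa is the size of a smallest set S of annotation terms such that every
#' gene carries at least one term of S.  Solved exactly by iterative
#' deepening over term combinations in lexicographic order, so the returned
#' cover is the lexicographically least among the minima.  A greedy cover
#' bounds the search depth.
#'
#' @param x either a character vector of gene ids or a [RepCycle-class]; for
#'   a cycle, `geneIds` maps vertex indices to gene ids.
#' @param ann an [AnnotationMap-class] covering all genes.
#' @param geneIds character vector indexed by cycle vertices (only used when
#'   `x` is a [RepCycle-class]).
#' @return A [CoverResult-class].
#' @examples
#' fx <- workedAnnotationExample()
#' kappaCover(fx$genes, fx$annotations)@kappa  # 3
#' @export
kappaCover <- function(x, ann, geneIds = NULL) {
  genes <- if (is(x, "RepCycle")) {
    stopIfNot(!is.null(geneIds), "geneIds required for a RepCycle input")
    geneIds[vertexSet(x)]
  } else as.character(x)
  stopIfNot(length(genes) > 0L, "empty cycle: no genes to cover")
  sets <- annotationTerms(ann, genes)     # errors on missing genes
  vocabLocal <- sort(unique(unlist(sets, use.names = FALSE)))
  covers <- vapply(vocabLocal,
                   function(t) vapply(sets, function(s) t %in% s, logical(1)),
                   logical(length(sets)))
  covers <- matrix(covers, nrow = length(sets),
                   dimnames = list(genes, vocabLocal))
  greedy <- greedySetCover(covers)
  sol <- NULL
  for (s in seq_len(length(greedy))) {
    sol <- coverSearchRec(covers, s, 1L, rep(TRUE, nrow(covers)))
    if (!is.null(sol)) break
  }
  cover <- vocabLocal[sol]
  new("CoverResult", kappa = length(cover), cover = cover,
      genes = unique(genes))
}

#' Curate genes through low-kappa cycles
#'
#' Builds the gene point cloud, extracts the top `k` cycles per requested
#' homology dimension, computes kappa per cycle, and selects the union of the
#' vertex sets of cycles with `kappa <= kappaMax`; the curated dataset
#' preserves the original column order.  Genes absent from `ann` are assigned
#' the reserved term (see [completeAnnotations()]).
#'
#' @param ds an [ExpressionDataset-class].
#' @param ann an [AnnotationMap-class].
#' @param k cycles considered per homology dimension (default 100).
#' @param kappaMax selection threshold (default 3); `Inf` keeps all cycles.
#' @param dims homology dimensions to use, a subset of `c(1, 2)`.
#' @param scaling,maxScale,sparsity,h1Weights,h2Weights as in
#'   [curateCohorts()].
#' @return A [GeneCurationResult-class].
#' @export
curateGenes <- function(ds, ann, k = 100L, kappaMax = 3, dims = c(1L, 2L),
                        scaling = "none", maxScale = NULL, sparsity = NULL,
                        h1Weights = "euclidean",
                        h2Weights = "filtration_value") {
  k <- as.integer(k)
  stopIfNot(k >= 0L, "k must be >= 0")
  stopIfNot(kappaMax >= 1, "kappaMax must be >= 1")
  dims <- sort(unique(as.integer(dims)))
  stopIfNot(all(dims %in% c(1L, 2L)), "dims must be a subset of {1,2}")
  ann <- completeAnnotations(ann, geneIds(ds))
  pc <- genesToPointCloud(ds, scaling)

  covers <- list(); cycles <- list(); selectedIdx <- integer(0)
  if (k > 0L) {
    run <- topCyclesForCloud(pc, dims, k, maxScale = maxScale,
                             sparsity = sparsity, h1Weights = h1Weights,
                             h2Weights = h2Weights)
    cycles <- run$cycles
    covers <- lapply(cycles, function(cy)
      kappaCover(cy, ann, geneIds = pc@pointIds))
    keep <- vapply(covers, function(cv) cv@kappa <= kappaMax, logical(1))
    if (!any(keep))
      warning("no cycle satisfies the kappa threshold; selection is empty",
              call. = FALSE)
    selectedIdx <- sort(unique(unlist(lapply(cycles[keep], vertexSet))))
  }
  selected <- pc@pointIds[selectedIdx]
  curated <- if (length(selected)) selectGenes(ds, selected) else NULL
  new("GeneCurationResult", selectedGenes = selected,
      kappaMax = as.numeric(kappaMax), covers = covers, cycles = cycles,
      curated = curated)
}

#' Export cover results as JSON
#'
#' @param covers list of [CoverResult-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCovers <- function(covers, path) {
  recs <- lapply(covers, function(cv) list(
    kappa = cv@kappa, cover = as.list(cv@cover), genes = as.list(cv@genes)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
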