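## Central S4 classes.  Filtration indices are 0-based throughout the
## user-facing interval tables (position i+1 in the simplex list has
## filtration index i), matching the usual insertion-index convention of
## persistence computations.

#' Point cloud with identifiers and optional integer labels
#'
#' @slot coords numeric matrix, one row per point.
#' @slot pointIds character, unique identifiers, one per point.
#' @slot labels integer, one per point; may be NA when points are unlabeled
#'   (e.g. gene point clouds).
#' @export
setClass("PointCloud",
         slots = c(coords = "matrix", pointIds = "character",
                   labels = "integer"))

setValidity("PointCloud", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("point cloud must contain at least one point")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@pointIds) != n) return("pointIds must have one id per point")
  if (anyDuplicated(object@pointIds)) return("pointIds must be unique")
  if (length(object@labels) != n) return("labels must have one entry per point")
  TRUE
})

#' Construct a PointCloud
#'
#' @param coords numeric matrix of coordinates, one row per point.
#' @param pointIds character identifiers; defaults to rownames or `p1..pn`.
#' @param labels optional integer labels, one per point.
#' @return A [PointCloud-class] object.
#' @export
PointCloud <- function(coords, pointIds = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(pointIds)) pointIds <- rownames(coords) %||% paste0("p", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  new("PointCloud", coords = coords, pointIds = as.character(pointIds),
      labels = as.integer(labels))
}

#' Ordered simplicial filtration
#'
#' Simplices are stored in filtration order with non-decreasing values; every
#' proper face precedes its cofaces.  Vertices are positive integers indexing
#' the rows of `coords` when coordinates are available.
#'
#' @slot simplices list of strictly increasing integer vectors.
#' @slot values numeric filtration value per simplex, non-decreasing.
#' @slot dims integer simplex dimension per simplex (0..3).
#' @slot coords numeric matrix of point coordinates (0-row when abstract).
#' @slot isPseudoManifold logical flag set by [pseudoManifoldize()].
#' @export
setClass("Filtration",
         slots = c(simplices = "list", values = "numeric", dims = "integer",
                   coords = "matrix", isPseudoManifold = "logical"))

## all facet keys of the simplices at positions `which`, together with the
## owning position repeated per facet
allFacetKeys <- function(simplices, which) {
  keys <- unlist(lapply(simplices[which], function(v)
    vapply(seq_along(v), function(i) simplexKey(v[-i]), character(1))),
    use.names = FALSE)
  list(keys = keys,
       owner = rep(which, lengths(simplices[which])))
}

validateFiltrationStructure <- function(simplices, values, dims) {
  k <- length(simplices)
  if (k == 0L) return("filtration is empty")
  if (length(values) != k || length(dims) != k)
    return("values/dims length mismatch")
  bad <- which(vapply(simplices, function(v)
    anyDuplicated(v) > 0L || is.unsorted(v, strictly = TRUE), logical(1)))
  if (length(bad))
    return(sprintf("simplex %s is not a strictly increasing vertex tuple",
                   simplexKey(simplices[[bad[1L]]])))
  if (any(dims != lengths(simplices) - 1L) || any(dims > 3L))
    return("simplex with unsupported dimension")
  if (is.unsorted(values)) return("filtration values must be non-decreasing")
  keys <- vapply(simplices, simplexKey, character(1))
  if (anyDuplicated(keys)) return("duplicate simplices in filtration")
  hi <- which(dims >= 1L)
  if (length(hi)) {
    fc <- allFacetKeys(simplices, hi)
    fp <- match(fc$keys, keys)
    wrong <- is.na(fp) | fp >= fc$owner
    if (any(wrong)) {
      w <- which(wrong)[1L]
      return(sprintf(
        "face %s of simplex %s is missing or appears at a later index",
        fc$keys[w], keys[fc$owner[w]]))
    }
  }
  TRUE
}

setValidity("Filtration", function(object) {
  validateFiltrationStructure(object@simplices, object@values, object@dims)
})

#' Construct a Filtration from an ordered simplex list
#'
#' @param simplices list of integer vertex vectors in filtration order.
#' @param values numeric filtration values, non-decreasing along the order.
#' @param coords optional coordinate matrix for the vertices.
#' @param isPseudoManifold logical; set TRUE only when every triangle is known
#'   to have at most two tetrahedral cofacets.
#' @return A [Filtration-class] object.
#' @export
Filtration <- function(simplices, values, coords = NULL,
                       isPseudoManifold = FALSE) {
  simplices <- lapply(simplices, function(v) sort(as.integer(v)))
  if (is.null(coords)) coords <- matrix(numeric(0), 0L, 0L)
  coords <- as.matrix(coords)
  new("Filtration", simplices = simplices, values = as.numeric(values),
      dims = vapply(simplices, length, integer(1)) - 1L,
      coords = coords, isPseudoManifold = isPseudoManifold)
}

#' Representative persistent cycle
#'
#' A d-cycle attached to a finite persistence interval: an edge set for d = 1,
#' a triangle set for d = 2.  The Z/2 boundary of the simplex set is empty and
#' every member simplex has filtration index at most the birth index.
#'
#' @slot dim integer homology dimension (1 or 2).
#' @slot simplices list of integer vertex vectors of that dimension.
#' @slot birth,death integer 0-based filtration indices of creator/destroyer.
#' @slot birthValue,deathValue numeric filtration values of the interval.
#' @export
setClass("RepCycle",
         slots = c(dim = "integer", simplices = "list",
                   birth = "integer", death = "integer",
                   birthValue = "numeric", deathValue = "numeric"))

setValidity("RepCycle", function(object) {
  if (!object@dim %in% c(1L, 2L)) return("cycle dimension must be 1 or 2")
  if (length(object@simplices) == 0L) return("cycle has no simplices")
  len <- vapply(object@simplices, length, integer(1))
  if (!all(len == object@dim + 1L))
    return("all member simplices must have the cycle dimension")
  if (!z2BoundaryIsZero(object@simplices))
    return("Z/2 boundary of the simplex set is not empty")
  if (object@birthValue > object@deathValue)
    return("birth value exceeds death value")
  TRUE
})

#' Construct a RepCycle
#'
#' @param dim homology dimension, 1 or 2.
#' @param simplices list of integer vertex vectors of that dimension whose
#'   Z/2 boundary is empty.
#' @param birth,death 0-based filtration indices of creator and destroyer.
#' @param birthValue,deathValue filtration values of the interval.
#' @return A [RepCycle-class].
#' @export
RepCycle <- function(dim, simplices, birth, death, birthValue, deathValue) {
  new("RepCycle", dim = as.integer(dim),
      simplices = lapply(simplices, function(v) sort(as.integer(v))),
      birth = as.integer(birth), death = as.integer(death),
      birthValue = as.numeric(birthValue), deathValue = as.numeric(deathValue))
}

#' Expression dataset: cohorts, genes and phenotype labels
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding the
#' cohort-by-gene matrix as an `exprs` assay (genes in rows, cohorts in
#' columns, the Bioconductor orientation) with the integer phenotype in
#' `colData(x)$phenotype`.  The canonical user-facing orientation is cohorts
#' in rows ([exprsValues()]).
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  if (nrow(object) < 1L) return("dataset must contain at least one gene")
  if (!"phenotype" %in% colnames(colData(object)))
    return("colData must contain a 'phenotype' column")
  ph <- colData(object)$phenotype
  if (anyNA(ph)) return("every cohort must have a phenotype label")
  if (!is.integer(ph)) return("phenotype labels must be integers")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is missing")
  if (!all(is.finite(assay(object, "exprs"))))
    return("expression values must be finite")
  if (anyDuplicated(colnames(object))) return("cohort ids must be unique")
  if (anyDuplicated(rownames(object))) return("gene ids must be unique")
  TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix with cohorts in rows and genes in columns.
#' @param labels integer phenotype labels, either unnamed in row order or
#'   named by cohort id.
#' @param cohortIds,geneIds identifiers; default to dimnames of `values`.
#' @return An [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(values, labels,
                              cohortIds = rownames(values),
                              geneIds = colnames(values)) {
  values <- as.matrix(values)
  n <- nrow(values); m <- ncol(values)
  stopIfNot(n >= 1L && m >= 1L, "expression matrix must be at least 1 x 1")
  if (is.null(cohortIds)) cohortIds <- paste0("c", seq_len(n))
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(m))
  cohortIds <- as.character(cohortIds); geneIds <- as.character(geneIds)
  if (!is.null(names(labels))) {
    miss <- setdiff(cohortIds, names(labels))
    if (length(miss))
      stop("cohorts without a label: ", paste(miss, collapse = ", "),
           call. = FALSE)
    labels <- labels[cohortIds]
  }
  stopIfNot(length(labels) == n, "labels must cover every cohort")
  a <- t(values)
  dimnames(a) <- list(geneIds, cohortIds)
  se <- SummarizedExperiment(assays = list(exprs = a),
                             colData = DataFrame(phenotype = as.integer(labels),
                                                 row.names = cohortIds))
  new("ExpressionDataset", se)
}

#' Gene-to-term annotation map
#'
#' Maps each gene id to a non-empty set of functional terms; genes lacking
#' curation carry the reserved term given by [notAnnotatedTerm()].
#'
#' @slot terms named list of character vectors, one per gene.
#' @export
setClass("AnnotationMap", slots = c(terms = "list"))

setValidity("AnnotationMap", function(object) {
  if (length(object@terms) == 0L) return("annotation map is empty")
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
    return("terms must be uniquely named by gene id")
  ok <- vapply(object@terms, function(t)
    is.character(t) && length(t) >= 1L && !anyNA(t) && !anyDuplicated(t),
    logical(1))
  if (!all(ok)) return("every gene must map to a non-empty set of terms")
  TRUE
})

#' Construct an AnnotationMap
#'
#' @param x either a named list of character term vectors, or a data.frame
#'   with columns `gene` and `term` (many-to-many rows are aggregated).
#' @return An [AnnotationMap-class].
#' @export
AnnotationMap <- function(x) {
  if (is.data.frame(x)) {
    stopIfNot(ncol(x) >= 2L, "annotation table needs gene and term columns")
    g <- as.character(x[[1]]); t <- as.character(x[[2]])
    x <- lapply(split(t, g), function(ts) sort(unique(ts)))
  }
  terms <- lapply(x, function(t) sort(unique(as.character(t))))
  new("AnnotationMap", terms = terms)
}

#' Label dominance of a representative cycle
#'
#' @slot cycle the [RepCycle-class] examined.
#' @slot labelCounts named integer, count per label over the cycle vertices.
#' @slot dominant logical, TRUE iff the maximal count reaches
#'   `floor(|Vert(Z)|/2)`.
#' @slot dominatingLabel integer label, NA when not dominant.
#' @slot dominanceRatio numeric, maximal count / number of cycle vertices.
#' @export
setClass("DominanceReport",
         slots = c(cycle = "RepCycle", labelCounts = "integer",
                   dominant = "logical", dominatingLabel = "integer",
                   dominanceRatio = "numeric"))

#' Result of dominant-cycle cohort curation
#'
#' @slot selectedCohorts ordered character vector of curated cohort ids.
#' @slot mode character, one of "H1", "H2", "H1+H2".
#' @slot k integer, cycles considered per homology dimension.
#' @slot reports list of [DominanceReport-class], one per extracted cycle.
#' @slot cycles list of [RepCycle-class].
#' @slot curated the curated [ExpressionDataset-class] (original row order).
#' @export
setClass("CurationResult",
         slots = c(selectedCohorts = "character", mode = "character",
                   k = "integer", reports = "list", cycles = "list",
                   curated = "ANY"))

#' Minimum annotation cover of a representative cycle
#'
#' @slot kappa integer, size of a minimum covering term set.
#' @slot cover character, the lexicographically least minimum cover.
#' @slot genes character, gene ids of the cycle vertices.
#' @export
setClass("CoverResult",
         slots = c(kappa = "integer", cover = "character", genes = "character"))

#' Result of kappa-based gene curation
#'
#' @slot selectedGenes character, curated gene ids in original column order.
#' @slot kappaMax numeric threshold used.
#' @slot covers list of [CoverResult-class], one per extracted cycle.
#' @slot cycles list of [RepCycle-class].
#' @slot curated the curated [ExpressionDataset-class].
#' @export
setClass("GeneCurationResult",
         slots = c(selectedGenes = "character", kappaMax = "numeric",
                   covers = "list", cycles = "list", curated = "ANY"))

#' Cross-validated classification metrics
#'
#' @slot model character model name.
#' @slot folds data.frame with one row per repetition (accuracy, precision,
#'   recall, f1).
#' @slot means named numeric mean metrics over repetitions.
#' @slot nSamples,nFeatures integer problem size.
#' @export
setClass("MetricsTable",
         slots = c(model = "character", folds = "data.frame",
                   means = "numeric", nSamples = "integer",
                   nFeatures = "integer"))

#' Hyperparameters of the 1D convolutional classifier
#'
#' @slot nFilters,kernelSize,poolSize,nClasses,epochs,batchSize integers.
#' @slot dropoutProb numeric in (0,1).
#' @slot denseUnits integer vector of two strictly decreasing dense sizes.
#' @slot learningRate numeric Adam step size.
#' @slot seed integer seed for weight init, splits and dropout.
#' @export
setClass("CNNSpec",
         slots = c(nFilters = "integer", kernelSize = "integer",
                   poolSize = "integer", dropoutProb = "numeric",
                   denseUnits = "integer", nClasses = "integer",
                   epochs = "integer", learningRate = "numeric",
                   batchSize = "integer", seed = "integer"))

setValidity("CNNSpec", function(object) {
  if (object@poolSize != 2L) return("pool size is fixed at 2")
  if (!(object@dropoutProb > 0 && object@dropoutProb < 1))
    return("dropout probability must lie in (0,1)")
  if (length(object@denseUnits) != 2L ||
      diff(object@denseUnits) >= 0L)
    return("denseUnits must be two strictly decreasing sizes")
  if (object@nClasses < 2L) return("at least two classes required")
  if (object@epochs < 0L) return("epochs must be non-negative")
  TRUE
})

#' Construct a CNNSpec
#'
#' Defaults: 32 filters, kernel 16, pool 2, dropout 0.25, dense 128 -> 64,
#' 50 epochs, Adam with learning rate 1e-3.
#'
#' @param nClasses number of phenotype classes.
#' @param nFilters,kernelSize,poolSize,dropoutProb,denseUnits,epochs
#'   architecture hyperparameters (see slots).
#' @param learningRate,batchSize,seed optimisation settings.
#' @return A [CNNSpec-class].
#' @export
cnnSpec <- function(nClasses, nFilters = 32L, kernelSize = 16L,
                    poolSize = 2L, dropoutProb = 0.25,
                    denseUnits = c(128L, 64L), epochs = 50L,
                    learningRate = 1e-3, batchSize = 32L, seed = 1L) {
  new("CNNSpec", nFilters = as.integer(nFilters),
      kernelSize = as.integer(kernelSize), poolSize = as.integer(poolSize),
      dropoutProb = dropoutProb, denseUnits = as.integer(denseUnits),
      nClasses = as.integer(nClasses), epochs = as.integer(epochs),
      learningRate = learningRate, batchSize = as.integer(batchSize),
      seed = as.integer(seed))
}

#' Fitted 1D CNN with per-epoch traces
#'
#' @slot spec the [CNNSpec-class] used.
#' @slot history data.frame of per-epoch loss/accuracy/f1 for train and test.
#' @slot trainMetrics,testMetrics named numeric final metrics.
#' @slot testProbabilities numeric matrix of softmax outputs on the test set.
#' @slot geneOrder character, feature order fed to the network.
#' @export
setClass("CnnResult",
         slots = c(spec = "CNNSpec", history = "data.frame",
                   trainMetrics = "numeric", testMetrics = "numeric",
                   testProbabilities = "matrix", geneOrder = "character"))

#' Configuration for the planted-cohort generator
#'
#' @slot nPerClass integer counts per class.
#' @slot m integer ambient dimension (number of synthetic genes).
#' @slot structures list, one per class: `list(type, center, radius)` with
#'   type in sphere, circle, torus, gaussian_blob; `center` is recycled to
#'   length m, the structure occupies the leading coordinates.
#' @slot noiseSd numeric isotropic noise standard deviation.
#' @slot outlierFraction numeric in [0,1).
#' @slot seed integer.
#' @export
setClass("PlantedCohortConfig",
         slots = c(nPerClass = "integer", m = "integer", structures = "list",
                   noiseSd = "numeric", outlierFraction = "numeric",
                   seed = "integer"))

setValidity("PlantedCohortConfig", function(object) {
  if (length(object@nPerClass) != length(object@structures))
    return("one structure per class is required")
  if (any(object@nPerClass < 1L)) return("each class needs at least one cohort")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@outlierFraction < 0 || object@outlierFraction >= 1)
    return("outlierFraction must lie in [0,1)")
  ok <- vapply(object@structures, function(s)
    is.list(s) && s$type %in% c("sphere", "circle", "torus", "gaussian_blob"),
    logical(1))
  if (!all(ok)) return("unknown structure type")
  TRUE
})
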