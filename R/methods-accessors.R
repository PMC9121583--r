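#' @describeIn nSimplices number of simplices
#' @export
setMethod("nSimplices", "Filtration", function(x) length(x@simplices))

#' @describeIn simplexList simplices in filtration order
#' @export
setMethod("simplexList", "Filtration", function(x) x@simplices)

#' @describeIn simplexValues filtration values
#' @export
setMethod("simplexValues", "Filtration", function(x) x@values)

#' @describeIn simplexDims simplex dimensions
#' @export
setMethod("simplexDims", "Filtration", function(x) x@dims)

#' Coordinates attached to a filtration
#' @param filt a [Filtration-class].
#' @return Numeric matrix (0-row when the filtration is abstract).
#' @export
pointCoords <- function(filt) filt@coords

#' Whether a filtration is flagged as a pseudo-manifold
#' @param filt a [Filtration-class].
#' @return Logical.
#' @export
isPseudoManifold <- function(filt) filt@isPseudoManifold

#' 0-based filtration index of a simplex
#'
#' @param filt a [Filtration-class].
#' @param vertices integer vertex vector.
#' @return Integer index, or NA when the simplex is absent.
#' @export
simplexIndex <- function(filt, vertices) {
  key <- simplexKey(sort(as.integer(vertices)))
  keys <- vapply(filt@simplices, simplexKey, character(1))
  i <- match(key, keys)
  if (is.na(i)) NA_integer_ else i - 1L
}

setMethod("show", "Filtration", function(object) {
  tab <- table(factor(object@dims, levels = 0:3))
  cat(sprintf("Filtration with %d simplices (%s)%s\n", length(object@simplices),
              paste(sprintf("%s of dim %s", tab, names(tab))[tab > 0],
                    collapse = ", "),
              if (object@isPseudoManifold) " [pseudo-manifold]" else ""))
  cat(sprintf("  values in [%g, %g]\n", min(object@values), max(object@values)))
})

#' @describeIn vertexSet union of member-simplex vertices
#' @export
setMethod("vertexSet", "RepCycle", function(x)
  sort(unique(unlist(x@simplices, use.names = FALSE))))

#' @describeIn cycleSimplices member simplices
#' @export
setMethod("cycleSimplices", "RepCycle", function(x) x@simplices)

setMethod("show", "RepCycle", function(object) {
  cat(sprintf("RepCycle: dim %d, %d simplices, %d vertices, interval [%g, %g)\n",
              object@dim, length(object@simplices), length(vertexSet(object)),
              object@birthValue, object@deathValue))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in %d dimensions (%s)\n",
              nrow(object@coords), ncol(object@coords),
              if (all(is.na(object@labels))) "unlabeled" else "labeled"))
})

#' @describeIn cohortIds cohort ids (columns of the underlying assay)
#' @export
setMethod("cohortIds", "ExpressionDataset", function(x) colnames(x))

#' @describeIn geneIds gene ids (rows of the underlying assay)
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))

#' @describeIn phenotype named integer labels
#' @export
setMethod("phenotype", "ExpressionDataset", function(x) {
  ph <- colData(x)$phenotype
  names(ph) <- colnames(x)
  ph
})

#' @describeIn exprsValues cohorts-in-rows matrix
#' @export
setMethod("exprsValues", "ExpressionDataset", function(x) t(assay(x, "exprs")))

#' Restrict a dataset to a subset of cohorts
#' @param ds an [ExpressionDataset-class].
#' @param ids cohort ids to keep; original row order is preserved.
#' @return An [ExpressionDataset-class].
#' @export
selectCohorts <- function(ds, ids) {
  keep <- cohortIds(ds)[cohortIds(ds) %in% ids]
  ds[, keep]
}

#' Restrict a dataset to a subset of genes
#' @param ds an [ExpressionDataset-class].
#' @param ids gene ids to keep; original column order is preserved.
#' @return An [ExpressionDataset-class].
#' @export
selectGenes <- function(ds, ids) {
  keep <- geneIds(ds)[geneIds(ds) %in% ids]
  ds[keep, ]
}

#' @describeIn annotationTerms term sets, optionally restricted to `genes`
#' @export
setMethod("annotationTerms", "AnnotationMap", function(x, genes = NULL) {
  if (is.null(genes)) return(x@terms)
  miss <- setdiff(genes, names(x@terms))
  if (length(miss))
    stop("genes missing from the annotation map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x@terms[genes]
})

#' @describeIn vocabulary sorted union of all term sets
#' @export
setMethod("vocabulary", "AnnotationMap", function(x)
  sort(unique(unlist(x@terms, use.names = FALSE))))

setMethod("show", "AnnotationMap", function(object) {
  cat(sprintf("AnnotationMap: %d genes, %d terms\n",
              length(object@terms), length(vocabulary(object))))
})

#' Add the reserved term for genes absent from an annotation map
#'
#' @param ann an [AnnotationMap-class].
#' @param genes character vector of gene ids that must all be annotated.
#' @param warn logical, emit a warning listing the completed genes.
#' @return An [AnnotationMap-class] covering all `genes`.
#' @export
completeAnnotations <- function(ann, genes, warn = TRUE) {
  miss <- setdiff(genes, names(ann@terms))
  if (length(miss) == 0L) return(ann)
  if (warn)
    warning(sprintf("%d gene(s) without annotation assigned '%s'",
                    length(miss), notAnnotatedTerm()), call. = FALSE)
  extra <- stats::setNames(rep(list(notAnnotatedTerm()), length(miss)), miss)
  AnnotationMap(c(ann@terms, extra))
}

setMethod("show", "DominanceReport", function(object) {
  cat(sprintf("DominanceReport: %s (label %s, ratio %.3f); counts: %s\n",
              if (object@dominant) "dominant" else "not dominant",
              ifelse(is.na(object@dominatingLabel), "-",
                     object@dominatingLabel),
              object@dominanceRatio,
              paste(sprintf("%s:%d", names(object@labelCounts),
                            object@labelCounts), collapse = " ")))
})

#' @describeIn selectedCohorts curated cohort ids
#' @export
setMethod("selectedCohorts", "CurationResult", function(x) x@selectedCohorts)

#' @describeIn curatedDataset curated cohort subset
#' @export
setMethod("curatedDataset", "CurationResult", function(x) x@curated)

setMethod("show", "CurationResult", function(object) {
  nd <- sum(vapply(object@reports, function(r) r@dominant, logical(1)))
  cat(sprintf(
    "CurationResult (%s, k = %d): %d/%d dominant cycles, %d cohorts selected\n",
    object@mode, object@k, nd, length(object@reports),
    length(object@selectedCohorts)))
})

#' @describeIn selectedGenes curated gene ids
#' @export
setMethod("selectedGenes", "GeneCurationResult", function(x) x@selectedGenes)

#' @describeIn curatedDataset curated gene subset
#' @export
setMethod("curatedDataset", "GeneCurationResult", function(x) x@curated)

setMethod("show", "GeneCurationResult", function(object) {
  kap <- vapply(object@covers, function(cv) cv@kappa, integer(1))
  cat(sprintf(
    "GeneCurationResult (kappaMax = %g): %d cycles (kappa %s), %d genes selected\n",
    object@kappaMax, length(object@covers),
    if (length(kap)) paste(range(kap), collapse = "-") else "-",
    length(object@selectedGenes)))
})

setMethod("show", "CoverResult", function(object) {
  cat(sprintf("CoverResult: kappa = %d over %d genes; cover {%s}\n",
              object@kappa, length(object@genes),
              paste(object@cover, collapse = ", ")))
})

setMethod("show", "MetricsTable", function(object) {
  cat(sprintf("MetricsTable [%s] (%d reps, %d samples x %d features)\n",
              object@model, nrow(object@folds), object@nSamples,
              object@nFeatures))
  print(round(object@means, 4))
})

setMethod("show", "CnnResult", function(object) {
  cat("CnnResult\n  train:", paste(sprintf("%s=%.4f",
      names(object@trainMetrics), object@trainMetrics), collapse = " "),
      "\n  test: ", paste(sprintf("%s=%.4f",
      names(object@testMetrics), object@testMetrics), collapse = " "), "\n")
})
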