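#' Number of simplices in a filtration
#' @param x a [Filtration-class].
#' @return Integer count.
#' @export
setGeneric("nSimplices", function(x) standardGeneric("nSimplices"))

#' Simplex list of a filtration
#' @param x a [Filtration-class].
#' @return List of integer vertex vectors in filtration order.
#' @export
setGeneric("simplexList", function(x) standardGeneric("simplexList"))

#' Filtration values
#' @param x a [Filtration-class].
#' @return Numeric vector, non-decreasing.
#' @export
setGeneric("simplexValues", function(x) standardGeneric("simplexValues"))

#' Simplex dimensions
#' @param x a [Filtration-class].
#' @return Integer vector of dimensions.
#' @export
setGeneric("simplexDims", function(x) standardGeneric("simplexDims"))

#' Vertex set of a representative cycle (Vert(Z))
#' @param x a [RepCycle-class].
#' @return Sorted integer vector of vertex indices.
#' @export
setGeneric("vertexSet", function(x) standardGeneric("vertexSet"))

#' Member simplices of a representative cycle
#' @param x a [RepCycle-class].
#' @return List of integer vertex vectors.
#' @export
setGeneric("cycleSimplices", function(x) standardGeneric("cycleSimplices"))

#' Cohort identifiers
#' @param x an [ExpressionDataset-class].
#' @return Character vector.
#' @export
setGeneric("cohortIds", function(x) standardGeneric("cohortIds"))

#' Gene identifiers
#' @param x an [ExpressionDataset-class].
#' @return Character vector.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Integer phenotype labels, named by cohort id
#' @param x an [ExpressionDataset-class].
#' @return Named integer vector.
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' Expression values with cohorts in rows and genes in columns
#' @param x an [ExpressionDataset-class].
#' @return Numeric matrix.
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' Annotation term sets
#' @param x an [AnnotationMap-class].
#' @param genes optional character vector restricting/ordering the result.
#' @return Named list of character term vectors.
#' @export
setGeneric("annotationTerms",
           function(x, genes = NULL) standardGeneric("annotationTerms"))

#' Annotation vocabulary (union of all term sets)
#' @param x an [AnnotationMap-class].
#' @return Sorted character vector.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Selected cohorts of a curation result
#' @param x a [CurationResult-class].
#' @return Character vector in original row order.
#' @export
setGeneric("selectedCohorts", function(x) standardGeneric("selectedCohorts"))

#' Selected genes of a gene-curation result
#' @param x a [GeneCurationResult-class].
#' @return Character vector in original column order.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' Curated dataset of a curation result
#' @param x a [CurationResult-class] or [GeneCurationResult-class].
#' @return An [ExpressionDataset-class], or NULL when the selection is empty.
#' @export
setGeneric("curatedDataset", function(x) standardGeneric("curatedDataset"))
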