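## Readers and writers for delimited expression matrices, labels and
## annotations.  The canonical orientation is cohorts in rows; gene-side
## analysis transposes internally, never in files.

detectDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a delimited expression matrix
#'
#' Expects a header row and a leading id column.  Inputs with genes in rows
#' are transposed to the canonical cohorts-in-rows orientation.
#'
#' @param path input file.
#' @param orientation `"cohorts_in_rows"` (default) or `"genes_in_rows"`.
#' @param delimiter field separator; auto-detected (tab/comma) when NULL.
#' @return A numeric matrix with cohort row names and gene column names.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("cohorts_in_rows",
                                                 "genes_in_rows"),
                                 delimiter = NULL) {
  orientation <- match.arg(orientation)
  stopIfNot(file.exists(path), paste("file not found:", path))
  delimiter <- delimiter %||% detectDelimiter(path)
  raw <- read.table(path, sep = delimiter, header = TRUE, row.names = NULL,
                    check.names = FALSE, colClasses = "character",
                    quote = "\"", comment.char = "")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cols <- colnames(raw)[-1L]
  if (anyDuplicated(cols))
    stop("duplicate column ids: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, nrow(raw), length(cols),
              dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], cols[j], raw[[j + 1L]][bad[1L]]),
           call. = FALSE)
    m[, j] <- v
  }
  if (orientation == "genes_in_rows") m <- t(m)
  m
}

#' Write an expression matrix (or dataset) as delimited text
#'
#' @param x numeric matrix (cohorts in rows) or [ExpressionDataset-class].
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @param idHeader name of the leading id column.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path, delimiter = "\t",
                                  idHeader = "cohort") {
  if (is(x, "ExpressionDataset")) x <- exprsValues(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idHeader
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotype labels
#'
#' Two-column delimited text: cohort id, integer label.
#'
#' @param path input file.
#' @param delimiter field separator; auto-detected when NULL.
#' @return Named integer vector.
#' @export
readLabels <- function(path, delimiter = NULL) {
  stopIfNot(file.exists(path), paste("file not found:", path))
  delimiter <- delimiter %||% detectDelimiter(path)
  raw <- read.table(path, sep = delimiter, header = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  stopIfNot(nrow(raw) > 0L, "empty label file")
  stopIfNot(ncol(raw) >= 2L, "label file needs two columns (id, label)")
  lab <- suppressWarnings(as.integer(raw[[2L]]))
  bad <- which(is.na(lab))
  if (length(bad))
    stop(sprintf("non-integer label for cohort '%s': '%s'",
                 raw[[1L]][bad[1L]], raw[[2L]][bad[1L]]), call. = FALSE)
  stats::setNames(lab, raw[[1L]])
}

#' Write phenotype labels
#' @param labels named integer vector.
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @return Invisibly, `path`.
#' @export
writeLabels <- function(labels, path, delimiter = "\t") {
  write.table(data.frame(names(labels), unname(labels)), path,
              sep = delimiter, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Two-column delimited text (gene, term); repeated gene rows aggregate into
#' term sets, duplicate (gene, term) rows collapse.
#'
#' @param path input file.
#' @param delimiter field separator; auto-detected when NULL.
#' @return An [AnnotationMap-class].
#' @export
readAnnotations <- function(path, delimiter = NULL) {
  stopIfNot(file.exists(path), paste("file not found:", path))
  delimiter <- delimiter %||% detectDelimiter(path)
  raw <- read.table(path, sep = delimiter, header = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  stopIfNot(nrow(raw) > 0L, "empty annotation file")
  stopIfNot(ncol(raw) >= 2L, "annotation file needs two columns (gene, term)")
  AnnotationMap(data.frame(gene = raw[[1L]], term = raw[[2L]],
                           stringsAsFactors = FALSE))
}

#' Write an annotation map
#' @param ann an [AnnotationMap-class].
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @return Invisibly, `path`.
#' @export
writeAnnotations <- function(ann, path, delimiter = "\t") {
  t <- annotationTerms(ann)
  df <- data.frame(gene = rep(names(t), lengths(t)),
                   term = unlist(t, use.names = FALSE))
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the reproducibility sidecar of an artifact
#'
#' Records the resolved configuration and seed that produced a written file
#' as `<path>.run.json`.
#'
#' @param path artifact path.
#' @param config named list of resolved settings.
#' @param seed integer seed used.
#' @return Invisibly, the sidecar path.
#' @export
writeRunSidecar <- function(path, config, seed) {
  sidecar <- paste0(path, ".run.json")
  jsonlite::write_json(list(config = config, seed = seed,
                            package = "TopoCurate",
                            version = as.character(utils::packageVersion("TopoCurate"))),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}
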