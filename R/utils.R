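`%||%` <- function(a, b) if (is.null(a)) b else a

## canonical text key for a simplex, vertices assumed sorted
simplexKey <- function(v) paste(v, collapse = ",")

#' Reserved annotation term for genes without curated function
#'
#' Genes absent from an annotation table are mapped to this term.  It behaves
#' as an ordinary coverable term in the kappa set-cover statistic.
#'
#' @return A length-one character string.
#' @export
notAnnotatedTerm <- function() "Not annotated"

## Z/2 boundary of a set of d-simplices is zero iff every (d-1)-face occurs
## an even number of times
z2BoundaryIsZero <- function(simplices) {
  if (length(simplices) == 0L) return(TRUE)
  faces <- unlist(lapply(simplices, function(v) {
    vapply(seq_along(v), function(i) simplexKey(v[-i]), character(1))
  }), use.names = FALSE)
  all(table(faces) %% 2L == 0L)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
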