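## Z/2 persistence pairing by boundary-matrix column reduction (Rcpp kernel).
## Interval tables use 0-based simplexwise filtration indices alongside the
## real filtration values; the creator of a dim-d class is the d-simplex
## inserted at the birth index, the destroyer the (d+1)-simplex at the death
## index.  A triangle always kills the youngest live 1-cycle, the standard
## reduction convention.

buildBoundaryColumns <- function(filt) {
  simp <- filt@simplices
  dims <- filt@dims
  k <- length(simp)
  keys <- vapply(simp, simplexKey, character(1))
  cols <- rep(list(integer(0)), k)
  hi <- which(dims >= 1L)
  if (length(hi)) {
    fc <- allFacetKeys(simp, hi)
    fi <- match(fc$keys, keys)
    wrong <- is.na(fi) | fi >= fc$owner
    if (any(wrong)) {
      w <- which(wrong)[1L]
      stop(sprintf(
        "malformed filtration: face of simplex %s (index %d) missing or later",
        keys[fc$owner[w]], fc$owner[w] - 1L), call. = FALSE)
    }
    byOwner <- split(as.integer(fi) - 1L, fc$owner)
    cols[as.integer(names(byOwner))] <- lapply(byOwner, sort)
  }
  cols
}

#' Compute persistence intervals of a filtration
#'
#' Standard Z/2 boundary-matrix reduction.  Each finite interval carries its
#' creator and destroyer simplices; essential classes are returned with
#' `death = NA` and `death_value = Inf`.
#'
#' @param filt a [Filtration-class].
#' @param maxHomDim maximal homology dimension to report (0, 1 or 2).
#' @return A data.frame with columns `dim`, `birth`, `death` (0-based
#'   simplexwise indices), `birth_value`, `death_value`, `creator`,
#'   `destroyer` (comma-joined vertex tuples, destroyer NA when essential).
#' @examples
#' f <- workedFiltrationExample()
#' p <- computePersistence(f, maxHomDim = 1)
#' subset(p, dim == 1)  # pairs with (birth_value, death_value) (4,9),(5,8),(6,7)
#' @export
computePersistence <- function(filt, maxHomDim = 2L) {
  stopIfNot(is(filt, "Filtration"), "filt must be a Filtration")
  maxHomDim <- as.integer(maxHomDim)
  stopIfNot(maxHomDim >= 0L && maxHomDim <= 2L, "maxHomDim must be 0, 1 or 2")
  cols <- buildBoundaryColumns(filt)
  kills <- reduce_boundary(cols)          # 0-based kill index or -1
  k <- length(kills)
  dims <- filt@dims
  vals <- filt@values
  keys <- vapply(filt@simplices, simplexKey, character(1))

  destroyerPos <- which(kills >= 0L)      # 1-based positions of destroyers
  creatorPos <- kills[destroyerPos] + 1L  # 1-based positions of creators
  finKeep <- dims[creatorPos] <= maxHomDim
  essentialPos <- setdiff(which(kills == -1L), creatorPos)
  essKeep <- dims[essentialPos] <= maxHomDim

  out <- data.frame(
    dim = c(dims[creatorPos][finKeep], dims[essentialPos][essKeep]),
    birth = c(creatorPos[finKeep], essentialPos[essKeep]) - 1L,
    death = c(destroyerPos[finKeep] - 1L,
              rep(NA_integer_, sum(essKeep))),
    birth_value = c(vals[creatorPos][finKeep], vals[essentialPos][essKeep]),
    death_value = c(vals[destroyerPos][finKeep], rep(Inf, sum(essKeep))),
    creator = c(keys[creatorPos][finKeep], keys[essentialPos][essKeep]),
    destroyer = c(keys[destroyerPos][finKeep],
                  rep(NA_character_, sum(essKeep))),
    stringsAsFactors = FALSE)
  out <- out[order(out$dim, out$birth), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Finite intervals of one homology dimension
#'
#' @param intervals a persistence table from [computePersistence()].
#' @param dim homology dimension to keep.
#' @return The finite rows of that dimension, original order preserved.
#' @export
finiteIntervals <- function(intervals, dim) {
  keep <- !is.na(intervals$death) & intervals$dim == dim
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k intervals by length
#'
#' Orders finite intervals by decreasing `death_value - birth_value`
#' (interval length delta - beta), ties broken by smaller birth index, and
#' keeps the first `k`.
#'
#' @param intervals a table of finite intervals.
#' @param k non-negative integer; all intervals are returned if fewer exist.
#' @return The selected rows, longest first.
#' @export
topKByLength <- function(intervals, k) {
  stopIfNot(is.numeric(k) && length(k) == 1L && k >= 0, "k must be >= 0")
  stopIfNot(all(!is.na(intervals$death)), "all intervals must be finite")
  if (nrow(intervals) == 0L || k == 0)
    return(intervals[integer(0), , drop = FALSE])
  len <- intervals$death_value - intervals$birth_value
  ord <- order(-len, intervals$birth)
  out <- intervals[head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a persistence table as TSV
#'
#' Columns: dim, birth_index, death_index, birth_value, death_value, creator,
#' destroyer.
#'
#' @param intervals a persistence table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeIntervals <- function(intervals, path) {
  out <- data.frame(dim = intervals$dim,
                    birth_index = intervals$birth,
                    death_index = intervals$death,
                    birth_value = intervals$birth_value,
                    death_value = intervals$death_value,
                    creator = intervals$creator,
                    destroyer = intervals$destroyer)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
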