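## Vietoris-Rips filtration construction.  Simplex value = diameter
## (maximum pairwise distance among its vertices); ties in value are ordered
## by (dimension, lexicographic vertex tuple) for deterministic pairing.

#' Enclosing radius of a point cloud
#'
#' The smallest scale at which some point is within distance of all others;
#' Rips homology in positive dimensions is trivial beyond it, so it is a
#' natural default for the maximal filtration scale.
#'
#' @param coords numeric coordinate matrix.
#' @return A single numeric value.
#' @export
enclosingRadius <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 1L) return(0)
  D <- as.matrix(dist(coords))
  min(apply(D, 1L, max))
}

## greedy-permutation insertion radii: lambda[i] = distance from point i to
## the nearest point selected before it (Inf for the first point)
greedyPermutationRadii <- function(D) {
  n <- nrow(D)
  lambda <- rep(NA_real_, n)
  lambda[1L] <- Inf
  mind <- D[1L, ]
  mind[1L] <- 0
  for (k in seq_len(n - 1L)) {
    i <- which.max(mind)
    lambda[i] <- mind[i]
    mind <- pmin(mind, D[i, ])
  }
  lambda
}

#' Build a (sparse) Vietoris-Rips filtration
#'
#' In exact mode every simplex whose vertex-set diameter is at most
#' `maxScale` is included, with filtration value equal to that diameter.
#' When `sparsity` is set, a sparse approximation is built instead: points
#' receive greedy-permutation insertion radii `lambda` and an edge `{i,j}` is
#' kept only when `d(i,j) <= 2*min(lambda_i, lambda_j)/sparsity`, so long
#' edges between well-covered points are pruned; higher simplices are the
#' cliques of the kept graph.  Exact mode is the reference path.
#'
#' @param points a [PointCloud-class] or a numeric coordinate matrix.
#' @param maxDim maximal simplex dimension, 1, 2 or 3.
#' @param maxScale maximal filtration value (diameter scale), must be > 0.
#' @param sparsity NULL for exact Rips, or an interleaving ratio in (0,1];
#'   0.9 is a reasonable default when approximation is wanted.
#' @return A [Filtration-class] with coordinates attached.
#' @examples
#' f <- ripsFiltration(rbind(c(0, 0), c(2, 0)), maxDim = 1, maxScale = 3)
#' nSimplices(f)  # 2 vertices and 1 edge at value 2
#' @export
ripsFiltration <- function(points, maxDim = 2L, maxScale, sparsity = NULL) {
  coords <- if (is(points, "PointCloud")) points@coords else as.matrix(points)
  storage.mode(coords) <- "double"
  stopIfNot(nrow(coords) >= 1L, "point cloud must not be empty")
  stopIfNot(all(is.finite(coords)), "coordinates must be finite")
  maxDim <- as.integer(maxDim)
  stopIfNot(maxDim %in% 1:3, "maxDim must be 1, 2 or 3")
  stopIfNot(is.numeric(maxScale) && maxScale > 0, "maxScale must be > 0")
  if (!is.null(sparsity))
    stopIfNot(sparsity > 0 && sparsity <= 1, "sparsity must lie in (0,1]")

  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  adj <- D <= maxScale
  diag(adj) <- FALSE
  if (!is.null(sparsity) && n > 1L) {
    lambda <- greedyPermutationRadii(D)
    lim <- 2 * outer(lambda, lambda, pmin) / sparsity
    adj <- adj & (D <= lim)
  }

  verts <- as.list(seq_len(n))
  vvals <- numeric(n)
  simplices <- verts
  values <- vvals
  dims <- rep(0L, n)

  em <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(em)) {
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    simplices <- c(simplices, lapply(seq_len(nrow(em)),
                                     function(r) c(em[r, 1L], em[r, 2L])))
    values <- c(values, D[em])
    dims <- c(dims, rep(1L, nrow(em)))
  }

  tris <- NULL
  if (maxDim >= 2L && nrow(em)) {
    tl <- vector("list", nrow(em))
    for (r in seq_len(nrow(em))) {
      i <- em[r, 1L]; j <- em[r, 2L]
      ks <- which(adj[i, ] & adj[j, ])
      ks <- ks[ks > j]
      if (length(ks))
        tl[[r]] <- cbind(i, j, ks,
                         pmax(D[i, j], D[i, ks], D[j, ks]))
    }
    tris <- do.call(rbind, tl)
    if (!is.null(tris) && nrow(tris)) {
      simplices <- c(simplices, lapply(seq_len(nrow(tris)),
                                       function(r) tris[r, 1:3]))
      values <- c(values, tris[, 4L])
      dims <- c(dims, rep(2L, nrow(tris)))
    }
  }

  if (maxDim >= 3L && !is.null(tris) && nrow(tris)) {
    ql <- vector("list", nrow(tris))
    for (r in seq_len(nrow(tris))) {
      i <- tris[r, 1L]; j <- tris[r, 2L]; k <- tris[r, 3L]
      ls <- which(adj[i, ] & adj[j, ] & adj[k, ])
      ls <- ls[ls > k]
      if (length(ls))
        ql[[r]] <- cbind(i, j, k, ls,
                         pmax(tris[r, 4L], D[i, ls], D[j, ls], D[k, ls]))
    }
    quads <- do.call(rbind, ql)
    if (!is.null(quads) && nrow(quads)) {
      simplices <- c(simplices, lapply(seq_len(nrow(quads)),
                                       function(r) quads[r, 1:4]))
      values <- c(values, quads[, 5L])
      dims <- c(dims, rep(3L, nrow(quads)))
    }
  }

  pad <- function(p) vapply(simplices, function(v)
    if (length(v) >= p) as.integer(v[p]) else 0L, integer(1))
  ord <- order(values, dims, pad(1L), pad(2L), pad(3L), pad(4L))
  Filtration(simplices[ord], values[ord], coords = coords)
}

#' Write a filtration as line-oriented text
#'
#' One simplex per line in filtration order: `value<TAB>v0,v1,...`.
#'
#' @param filt a [Filtration-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeFiltration <- function(filt, path) {
  lines <- sprintf("%.17g\t%s", filt@values,
                   vapply(filt@simplices, simplexKey, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a filtration written by [writeFiltration()]
#'
#' @param path input file path.
#' @param isPseudoManifold logical flag to set on the result.
#' @return A [Filtration-class] (abstract: no coordinates).
#' @export
readFiltration <- function(path, isPseudoManifold = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stopIfNot(length(lines) > 0L, "empty filtration file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed filtration line ", bad[1L], call. = FALSE)
  values <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  simplices <- lapply(parts, function(p)
    as.integer(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  Filtration(simplices, values, isPseudoManifold = isPseudoManifold)
}
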