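## Representative persistent cycles.
##
## H1: the creator edge plus the shortest path between its endpoints through
## the 1-skeleton present strictly before the birth index.  This is the
## shortest cycle at the birth complex; it is used as the interval's
## representative (an approximation: the class that actually dies at delta
## can differ by a linear combination, but the birth-time shortest cycle
## typically coincides with it in practice).
##
## H2: minimal persistent 2-cycle on a pseudo-manifold via a minimum s-t cut
## of the dual flow network (nodes = tetrahedra plus one infinite vertex,
## arcs = triangles).  Infinite capacities are modeled by contracting arc
## endpoints, never by large finite numbers.

intervalRow <- function(interval) {
  if (is.data.frame(interval)) {
    stopIfNot(nrow(interval) == 1L, "pass exactly one interval row")
    as.list(interval[1L, ])
  } else as.list(interval)
}

#' Representative 1-cycle of a finite H1 interval
#'
#' @param filt the [Filtration-class] on which the interval was computed.
#' @param interval one finite dim-1 row of a persistence table.
#' @param weightScheme `"euclidean"` (default; edge length from coordinates,
#'   falling back to the edge filtration value for abstract filtrations,
#'   identical for Rips) or `"hop"` (unit weights).
#' @return A [RepCycle-class] containing the creator edge.
#' @export
h1Cycle <- function(filt, interval, weightScheme = c("euclidean", "hop")) {
  weightScheme <- match.arg(weightScheme)
  iv <- intervalRow(interval)
  stopIfNot(iv$dim == 1L, "interval must have homology dimension 1")
  stopIfNot(!is.na(iv$death), "interval must be finite")
  birth <- as.integer(iv$birth)
  creator <- filt@simplices[[birth + 1L]]
  stopIfNot(length(creator) == 2L, "creator of an H1 interval must be an edge")

  idx0 <- seq_along(filt@simplices) - 1L
  eSel <- which(filt@dims == 1L & idx0 < birth)
  nv <- sum(filt@dims == 0L)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(eSel)) {
    ends <- do.call(rbind, filt@simplices[eSel])
    w <- switch(weightScheme,
      euclidean = if (nrow(filt@coords) > 0L)
        sqrt(rowSums((filt@coords[ends[, 1L], , drop = FALSE] -
                      filt@coords[ends[, 2L], , drop = FALSE])^2))
      else filt@values[eSel],
      hop = rep(1, length(eSel)))
    g <- igraph::add_edges(g, t(ends))
    igraph::E(g)$weight <- w
    igraph::E(g)$fidx <- eSel
  }
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = creator[1L], to = creator[2L],
    weights = igraph::E(g)$weight, output = "epath"))
  ep <- sp$epath[[1L]]
  if (length(ep) == 0L)
    stop("no path between creator endpoints before the birth index: ",
         "corrupted filtration", call. = FALSE)
  pathEdges <- filt@simplices[igraph::E(g)$fidx[as.integer(ep)]]
  RepCycle(1L, c(list(creator), pathEdges),
           birth = birth, death = as.integer(iv$death),
           birthValue = iv$birth_value, deathValue = iv$death_value)
}

#' Convert a filtration into a pseudo-manifold
#'
#' Keeps every simplex of dimension at most 2 and retains tetrahedra greedily
#' in filtration order: a tetrahedron is kept only when each of its four
#' triangles currently has fewer than two kept cofacets.  Every triangle of
#' the output therefore has at most two tetrahedral cofacets, as the H2
#' min-cut algorithm requires; for a triangle with three or more cofacets the
#' two earliest in the filtration are the ones retained.
#'
#' @param filt a [Filtration-class].
#' @return A [Filtration-class] flagged as pseudo-manifold, order and values
#'   inherited.
#' @export
pseudoManifoldize <- function(filt) {
  dims <- filt@dims
  tetra <- which(dims == 3L)
  keep <- rep(TRUE, length(dims))
  if (length(tetra)) {
    triPos <- which(dims == 2L)
    triKeys <- vapply(filt@simplices[triPos], simplexKey, character(1))
    fc <- allFacetKeys(filt@simplices, tetra)
    faceNo <- matrix(match(fc$keys, triKeys), nrow = 4L)  # col per tetra
    cnt <- integer(length(triPos))
    for (qi in seq_along(tetra)) {  # tetra already in filtration order
      tn <- faceNo[, qi]
      if (all(cnt[tn] < 2L)) cnt[tn] <- cnt[tn] + 1L
      else keep[tetra[qi]] <- FALSE
    }
  }
  Filtration(filt@simplices[keep], filt@values[keep],
             coords = if (nrow(filt@coords)) filt@coords else NULL,
             isPseudoManifold = TRUE)
}

## Interval-independent part of the dual graph: one node per tetrahedron
## plus the infinite vertex, the <=2 cofacet nodes per triangle.
h2Skeleton <- function(filt) {
  if (!filt@isPseudoManifold)
    stop("h2Cycle requires a pseudo-manifold; run pseudoManifoldize() first",
         call. = FALSE)
  dims <- filt@dims
  triPos <- which(dims == 2L)               # 1-based positions
  tetPos <- which(dims == 3L)
  triKeys <- vapply(filt@simplices[triPos], simplexKey, character(1))
  INF_NODE <- length(tetPos) + 1L
  cof1 <- rep(INF_NODE, length(triPos))     # first cofacet node per triangle
  cof2 <- rep(INF_NODE, length(triPos))
  faceNo <- if (length(tetPos)) {
    fc <- allFacetKeys(filt@simplices, tetPos)
    matrix(match(fc$keys, triKeys), nrow = 4L)
  } else matrix(integer(0), 4L, 0L)
  for (qi in seq_along(tetPos)) {
    for (t in faceNo[, qi]) {
      if (cof1[t] == INF_NODE) cof1[t] <- qi
      else if (cof2[t] == INF_NODE) cof2[t] <- qi
      else stop("triangle with more than two cofacets: not a pseudo-manifold",
                call. = FALSE)
    }
  }
  list(triPos = triPos, tetPos = tetPos, cof1 = cof1, cof2 = cof2,
       infNode = INF_NODE)
}

## Dual flow network of a pseudo-manifold for one finite H2 interval.
## Nodes are tetrahedra (by 0-based filtration index) plus the infinite
## vertex; each triangle contributes one arc between its <=2 cofacets
## (missing sides attach to the infinite vertex).  Arcs of triangles
## inserted after the birth index carry infinite capacity.
h2DualNetwork <- function(filt, interval,
                          weightScheme = c("filtration_value", "unit"),
                          skeleton = NULL) {
  weightScheme <- match.arg(weightScheme)
  iv <- intervalRow(interval)
  stopIfNot(iv$dim == 2L, "interval must have homology dimension 2")
  stopIfNot(!is.na(iv$death), "interval must be finite")
  birth <- as.integer(iv$birth); death <- as.integer(iv$death)
  stopIfNot(length(filt@simplices[[death + 1L]]) == 4L,
            "destroyer of an H2 interval must be a tetrahedron")
  sk <- skeleton %||% h2Skeleton(filt)

  triIdx0 <- sk$triPos - 1L
  capacity <- ifelse(triIdx0 <= birth,
                     switch(weightScheme,
                            filtration_value = filt@values[sk$triPos],
                            unit = rep(1, length(sk$triPos))),
                     Inf)
  list(from = sk$cof1, to = sk$cof2, capacity = capacity,
       triangle = triIdx0, nTetra = length(sk$tetPos), infNode = sk$infNode,
       source = match(death + 1L, sk$tetPos),
       sinks = c(sk$infNode, which(sk$tetPos - 1L > death)))
}

ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Minimal persistent 2-cycle of a finite H2 interval
#'
#' Builds the dual flow network (source: the destroyer tetrahedron; sinks:
#' the infinite vertex together with tetrahedra inserted after the death
#' index), contracts the infinite-capacity arcs and the sink set, computes an
#' undirected minimum s-t cut, and returns the triangles dual to the cut
#' arcs.  On a pseudo-manifold this 2-chain is a cycle of minimal total
#' weight among persistent cycles of the interval.
#'
#' @param filt a pseudo-manifold [Filtration-class] (see
#'   [pseudoManifoldize()]).
#' @param interval one finite dim-2 row of a persistence table computed on
#'   `filt`.
#' @param weightScheme `"filtration_value"` (default) or `"unit"` triangle
#'   weights.
#' @return A [RepCycle-class] containing the creator triangle.
#' @export
h2Cycle <- function(filt, interval,
                    weightScheme = c("filtration_value", "unit"),
                    skeleton = NULL) {
  weightScheme <- match.arg(weightScheme)
  net <- h2DualNetwork(filt, interval, weightScheme, skeleton = skeleton)
  iv <- intervalRow(interval)

  nNodes <- net$nTetra + 1L
  parent <- seq_len(nNodes)
  union2 <- function(a, b) {
    ra <- ufFind(parent, a); rb <- ufFind(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (s in net$sinks) union2(net$sinks[1L], s)
  inf <- which(!is.finite(net$capacity))
  for (i in inf) union2(net$from[i], net$to[i])
  comp <- vapply(seq_len(nNodes), function(i) ufFind(parent, i), integer(1))

  srcC <- comp[net$source]
  snkC <- comp[net$infNode]
  if (srcC == snkC)
    stop("no finite-capacity cut separates the destroyer from the sink: ",
         "interval and complex are inconsistent", call. = FALSE)

  fin <- which(is.finite(net$capacity))
  ends <- cbind(comp[net$from[fin]], comp[net$to[fin]])
  useful <- ends[, 1L] != ends[, 2L]
  fin <- fin[useful]; ends <- ends[useful, , drop = FALSE]
  nodes <- sort(unique(c(as.vector(ends), srcC, snkC)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(matrix(match(ends, nodes), ncol = 2L)))
  mf <- igraph::max_flow(g, source = match(srcC, nodes),
                         target = match(snkC, nodes),
                         capacity = net$capacity[fin])
  cutTri <- net$triangle[fin[as.integer(mf$cut)]]   # 0-based indices

  simps <- filt@simplices[cutTri + 1L]
  if (!simplexKey(filt@simplices[[iv$birth + 1L]]) %in%
      vapply(simps, simplexKey, character(1)))
    stop("minimum cut does not contain the creator triangle: ",
         "interval and complex are inconsistent", call. = FALSE)
  cyc <- RepCycle(2L, simps, birth = as.integer(iv$birth),
                  death = as.integer(iv$death),
                  birthValue = iv$birth_value, deathValue = iv$death_value)
  attr(cyc, "cutWeight") <- sum(net$capacity[fin][as.integer(mf$cut)])
  attr(cyc, "flowValue") <- mf$value
  cyc
}

#' Representative cycles for a list of intervals
#'
#' Maps [h1Cycle()] or [h2Cycle()] over the rows of an interval table,
#' preserving order.  Failures are reported per interval; successful cycles
#' are still returned.
#'
#' @param filt a [Filtration-class] (pseudo-manifold for dim 2).
#' @param intervals finite intervals of homology dimension `dim`.
#' @param dim 1 or 2.
#' @param weightScheme forwarded to the cycle extractor.
#' @return A list with elements `cycles` (list of [RepCycle-class]) and
#'   `failures` (data.frame with columns `row` and `message`).
#' @export
cyclesForIntervals <- function(filt, intervals, dim, weightScheme = NULL) {
  dim <- as.integer(dim)
  stopIfNot(dim %in% c(1L, 2L), "dim must be 1 or 2")
  cycles <- list()
  failures <- data.frame(row = integer(0), message = character(0),
                         stringsAsFactors = FALSE)
  skeleton <- if (dim == 2L && nrow(intervals) > 0L) h2Skeleton(filt) else NULL
  for (r in seq_len(nrow(intervals))) {
    res <- tryCatch({
      if (dim == 1L) {
        if (is.null(weightScheme)) h1Cycle(filt, intervals[r, ])
        else h1Cycle(filt, intervals[r, ], weightScheme)
      } else {
        if (is.null(weightScheme)) h2Cycle(filt, intervals[r, ],
                                           skeleton = skeleton)
        else h2Cycle(filt, intervals[r, ], weightScheme, skeleton = skeleton)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(row = r, message = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      cycles[[length(cycles) + 1L]] <- res
    }
  }
  if (nrow(failures))
    warning(sprintf("cycle extraction failed for %d of %d interval(s)",
                    nrow(failures), nrow(intervals)), call. = FALSE)
  list(cycles = cycles, failures = failures)
}

#' Export cycles as JSON records
#'
#' Each record holds dim, birth_index, death_index, birth_value, death_value,
#' the member simplices and the vertex set.
#'
#' @param cycles list of [RepCycle-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCycles <- function(cycles, path) {
  recs <- lapply(cycles, function(cy) list(
    dim = cy@dim, birth_index = cy@birth, death_index = cy@death,
    birth_value = cy@birthValue, death_value = cy@deathValue,
    simplices = lapply(cy@simplices, as.integer),
    vertex_set = vertexSet(cy)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
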