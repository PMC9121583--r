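## Independent oracles: everything here recomputes results with naive methods
## and never touches the package's own reduction / min-cut / cover search.

## dense O(k^3) Z/2 column reduction over a logical boundary matrix
naiveReduction <- function(filt) {
  simp <- simplexList(filt)
  k <- length(simp)
  keys <- vapply(simp, function(v) paste(v, collapse = "-"), character(1))
  B <- matrix(FALSE, k, k)
  for (j in seq_len(k)) {
    v <- simp[[j]]
    if (length(v) > 1L)
      for (i in seq_along(v))
        B[match(paste(v[-i], collapse = "-"), keys), j] <- TRUE
  }
  low <- function(col) {
    w <- which(col)
    if (length(w)) max(w) else 0L
  }
  owner <- integer(k)
  for (j in seq_len(k)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L || owner[l] == 0L) break
      B[, j] <- xor(B[, j], B[, owner[l]])
    }
    l <- low(B[, j])
    if (l > 0L) owner[l] <- j
  }
  births <- which(owner > 0L)
  pairs <- data.frame(dim = lengths(simp[births]) - 1L,
                      birth = births - 1L, death = owner[births] - 1L)
  zeroCols <- which(vapply(seq_len(k), function(j) !any(B[, j]), logical(1)))
  essential <- setdiff(zeroCols, births)
  list(pairs = pairs[order(pairs$dim, pairs$birth), , drop = FALSE],
       essential = data.frame(dim = lengths(simp[essential]) - 1L,
                              birth = essential - 1L))
}

## Edmonds-Karp max flow on an undirected capacitated graph; infinite
## capacities are allowed (R's Inf arithmetic handles the residuals)
edmondsKarpMaxFlow <- function(n, from, to, cap, s, t) {
  C <- matrix(0, n, n)
  for (i in seq_along(from)) {
    if (from[i] == to[i]) next
    C[from[i], to[i]] <- C[from[i], to[i]] + cap[i]
    C[to[i], from[i]] <- C[to[i], from[i]] + cap[i]
  }
  flow <- 0
  repeat {
    par <- rep(0L, n)
    par[s] <- s
    q <- s
    while (length(q) && par[t] == 0L) {
      u <- q[1L]; q <- q[-1L]
      nx <- which(C[u, ] > 1e-12 & par == 0L)
      par[nx] <- u
      q <- c(q, nx)
    }
    if (par[t] == 0L) break
    path <- t; v <- t
    while (v != s) { v <- par[v]; path <- c(v, path) }
    u <- path[-length(path)]; w <- path[-1L]
    b <- min(C[cbind(u, w)])
    C[cbind(u, w)] <- C[cbind(u, w)] - b
    C[cbind(w, u)] <- C[cbind(w, u)] + b
    flow <- flow + b
  }
  flow
}

## exhaustive minimum set cover by enumerating all term subsets
exhaustiveMinCover <- function(sets) {
  vocab <- sort(unique(unlist(sets)))
  v <- length(vocab)
  stopifnot(v <= 20L)
  inc <- vapply(vocab, function(t)
    vapply(sets, function(s) t %in% s, logical(1)), logical(length(sets)))
  inc <- matrix(inc, nrow = length(sets))
  best <- v
  for (mask in seq_len(2^v - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(v) - 1L)))
    if (sum(sel) >= best) next
    if (all(rowSums(inc[, sel, drop = FALSE]) > 0L)) best <- sum(sel)
  }
  best
}

## GF(2) nullspace basis of a 0/1 matrix (columns = triangles)
gf2NullspaceBasis <- function(M) {
  M <- M %% 2L
  nr <- nrow(M); nc <- ncol(M)
  A <- M
  pivotCol <- integer(0)
  r <- 1L
  for (c in seq_len(nc)) {
    if (r > nr) break
    pr <- which(A[r:nr, c] == 1L)
    if (!length(pr)) next
    pr <- pr[1L] + r - 1L
    if (pr != r) { tmp <- A[r, ]; A[r, ] <- A[pr, ]; A[pr, ] <- tmp }
    hit <- which(A[, c] == 1L)
    hit <- hit[hit != r]
    if (length(hit)) A[hit, ] <- (A[hit, , drop = FALSE] +
                                  matrix(A[r, ], length(hit), nc,
                                         byrow = TRUE)) %% 2L
    pivotCol <- c(pivotCol, c)
    r <- r + 1L
  }
  free <- setdiff(seq_len(nc), pivotCol)
  basis <- lapply(free, function(f) {
    x <- integer(nc)
    x[f] <- 1L
    for (i in seq_along(pivotCol))
      x[pivotCol[i]] <- A[i, f]
    x
  })
  basis
}

## exhaustive minimum-weight Z/2 2-cycle containing a given triangle, over
## the triangles of a pseudo-manifold filtration inserted at or before
## `birth`; returns NULL when the cycle space is too large to enumerate
enumerateMin2Cycle <- function(filt, birth, weights = NULL) {
  dims <- simplexDims(filt)
  idx0 <- seq_len(nSimplices(filt)) - 1L
  triPos <- which(dims == 2L & idx0 <= birth)
  stopifnot(length(triPos) <= 60L)
  creatorLocal <- match(birth, triPos - 1L)
  stopifnot(!is.na(creatorLocal))
  simp <- simplexList(filt)
  edgeKeys <- unique(unlist(lapply(triPos, function(p) {
    v <- simp[[p]]
    vapply(seq_along(v), function(i) paste(v[-i], collapse = "-"),
           character(1))
  })))
  M <- matrix(0L, length(edgeKeys), length(triPos))
  for (jj in seq_along(triPos)) {
    v <- simp[[triPos[jj]]]
    fk <- vapply(seq_along(v), function(i) paste(v[-i], collapse = "-"),
                 character(1))
    M[match(fk, edgeKeys), jj] <- 1L
  }
  basis <- gf2NullspaceBasis(M)
  d <- length(basis)
  if (d == 0L || d > 14L) return(NULL)
  w <- weights %||% rep(1, length(triPos))
  best <- Inf; bestCycle <- NULL
  for (mask in seq_len(2^d - 1L)) {
    x <- integer(length(triPos))
    for (b in seq_len(d))
      if (bitwAnd(mask, 2^(b - 1L))) x <- (x + basis[[b]]) %% 2L
    if (x[creatorLocal] == 1L) {
      wt <- sum(w[x == 1L])
      if (wt < best) {
        best <- wt
        bestCycle <- triPos[x == 1L] - 1L
      }
    }
  }
  list(weight = best, triangles = bestCycle)
}

## perceptron convergence check for linear separability
isLinearlySeparable <- function(x, y, maxIter = 2000L) {
  y2 <- ifelse(y == y[1L], 1, -1)
  xa <- cbind(1, x)
  w <- numeric(ncol(xa))
  for (it in seq_len(maxIter)) {
    pred <- sign(xa %*% w)
    wrong <- which(pred != y2)
    if (!length(wrong)) return(TRUE)
    i <- wrong[1L]
    w <- w + y2[i] * xa[i, ]
  }
  FALSE
}

## independent per-class metric computation from first principles
handMetrics <- function(cm) {
  n <- nrow(cm)
  acc <- sum(diag(cm)) / sum(cm)
  ps <- rs <- numeric(n)
  for (i in seq_len(n)) {
    ps[i] <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
    rs[i] <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
  }
  p <- sum(ps) / n; r <- sum(rs) / n
  c(accuracy = acc, precision = p, recall = r,
    f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
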