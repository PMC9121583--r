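## Small 1D convolutional classifier, implemented directly in R:
## conv1d (sigmoid) -> max pool (2) -> dropout -> dense (ReLU) -> dropout ->
## dense (ReLU) -> dense -> softmax, cross-entropy loss, Adam optimiser.
## Features are ordered by functional annotation before entering the
## convolution so that genes sharing a function form contiguous blocks.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Layer output sizes of the 1D CNN
#'
#' @param spec a [CNNSpec-class].
#' @param inputLength number of input features.
#' @return Named list with conv, pool and flatten lengths.
#' @export
cnnShapes <- function(spec, inputLength) {
  stopIfNot(inputLength >= spec@kernelSize,
            "feature count is smaller than the convolution kernel")
  convLen <- inputLength - spec@kernelSize + 1L
  poolLen <- convLen %/% spec@poolSize
  list(conv = convLen, pool = poolLen, flatten = poolLen * spec@nFilters)
}

initCnnParams <- function(spec, inputLength) {
  sh <- cnnShapes(spec, inputLength)
  K <- spec@kernelSize; F <- spec@nFilters
  d1 <- spec@denseUnits[1L]; d2 <- spec@denseUnits[2L]; C <- spec@nClasses
  rn <- function(n, fanIn) rnorm(n, sd = sqrt(2 / fanIn))
  list(W1 = matrix(rn(K * F, K), K, F), b1 = numeric(F),
       Wd1 = matrix(rn(sh$flatten * d1, sh$flatten), sh$flatten, d1),
       bd1 = numeric(d1),
       Wd2 = matrix(rn(d1 * d2, d1), d1, d2), bd2 = numeric(d2),
       Wo = matrix(rn(d2 * C, d2), d2, C), bo = numeric(C))
}

im2col1d <- function(X, K) {
  B <- nrow(X); L <- ncol(X); Tlen <- L - K + 1L
  M <- matrix(0, B * Tlen, K)
  for (k in seq_len(K))
    M[, k] <- as.vector(t(X[, k:(k + Tlen - 1L), drop = FALSE]))
  M                                  # row (b-1)*Tlen + t  =  X[b, t+k-1]
}

cnnForward <- function(params, spec, X, training = FALSE) {
  B <- nrow(X); K <- spec@kernelSize; F <- spec@nFilters
  sh <- cnnShapes(spec, ncol(X))
  Tlen <- sh$conv; T2 <- sh$pool
  M <- im2col1d(X, K)
  Z1 <- sweep(M %*% params$W1, 2L, params$b1, "+")
  A1 <- sigmoid(Z1)
  ra <- as.vector(outer(2L * seq_len(T2) - 1L, (seq_len(B) - 1L) * Tlen, "+"))
  rb <- ra + 1L
  maskA <- A1[ra, , drop = FALSE] >= A1[rb, , drop = FALSE]
  P <- pmax(A1[ra, , drop = FALSE], A1[rb, , drop = FALSE]) # (B*T2) x F
  arr <- array(P, dim = c(T2, B, F))
  Fl <- t(matrix(aperm(arr, c(1L, 3L, 2L)), ncol = B))      # B x (T2*F)
  drop1 <- drop2 <- NULL
  p <- spec@dropoutProb
  if (training) {
    drop1 <- matrix((runif(length(Fl)) >= p) / (1 - p), nrow(Fl), ncol(Fl))
    Fl <- Fl * drop1
  }
  Zd1 <- sweep(Fl %*% params$Wd1, 2L, params$bd1, "+")
  H1 <- pmax(Zd1, 0)
  if (training) {
    drop2 <- matrix((runif(length(H1)) >= p) / (1 - p), nrow(H1), ncol(H1))
    H1 <- H1 * drop2
  }
  Zd2 <- sweep(H1 %*% params$Wd2, 2L, params$bd2, "+")
  H2 <- pmax(Zd2, 0)
  logits <- sweep(H2 %*% params$Wo, 2L, params$bo, "+")
  probs <- softmaxRows(logits)
  list(M = M, Z1 = Z1, A1 = A1, ra = ra, rb = rb, maskA = maskA,
       Fl = Fl, Zd1 = Zd1, H1 = H1, Zd2 = Zd2, H2 = H2, probs = probs,
       drop1 = drop1, drop2 = drop2, Tlen = Tlen, T2 = T2, B = B)
}

cnnBackward <- function(params, spec, fw, Y) {
  B <- fw$B; F <- spec@nFilters; T2 <- fw$T2; Tlen <- fw$Tlen
  dLogits <- (fw$probs - Y) / B
  grads <- list()
  grads$Wo <- crossprod(fw$H2, dLogits)
  grads$bo <- colSums(dLogits)
  dH2 <- tcrossprod(dLogits, params$Wo)
  dZd2 <- dH2 * (fw$Zd2 > 0)
  grads$Wd2 <- crossprod(fw$H1, dZd2)
  grads$bd2 <- colSums(dZd2)
  dH1 <- tcrossprod(dZd2, params$Wd2)
  if (!is.null(fw$drop2)) dH1 <- dH1 * fw$drop2
  dZd1 <- dH1 * (fw$Zd1 > 0)
  grads$Wd1 <- crossprod(fw$Fl, dZd1)
  grads$bd1 <- colSums(dZd1)
  dFl <- tcrossprod(dZd1, params$Wd1)
  if (!is.null(fw$drop1)) dFl <- dFl * fw$drop1
  arr <- aperm(array(t(dFl), dim = c(T2, F, B)), c(1L, 3L, 2L))
  dP <- matrix(arr, B * T2, F)
  dA1 <- matrix(0, B * Tlen, F)
  dA1[fw$ra, ] <- dP * fw$maskA
  dA1[fw$rb, ] <- dA1[fw$rb, , drop = FALSE] + dP * !fw$maskA
  dZ1 <- dA1 * fw$A1 * (1 - fw$A1)
  grads$W1 <- crossprod(fw$M, dZ1)
  grads$b1 <- colSums(dZ1)
  grads
}

adamStep <- function(state, params, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

cnnEvaluate <- function(params, spec, X, yIdx, levels) {
  probs <- cnnForward(params, spec, X, training = FALSE)$probs
  loss <- -mean(log(pmax(probs[cbind(seq_len(nrow(X)), yIdx)], 1e-12)))
  pred <- max.col(probs, ties.method = "first")
  cm <- confusionCounts(levels[yIdx], levels[pred], levels)
  m <- computeMetrics(unclass(cm))
  list(loss = loss, metrics = m, probs = probs)
}

#' Train and evaluate the 1D convolutional classifier
#'
#' Genes are ordered by [sortGenesByFunction()] when annotations are given,
#' features are standardised with training-set statistics, and the network is
#' trained with Adam on a stratified 80/20 split for `spec@epochs` epochs.
#' All randomness (split, weights, dropout, batches) is governed by
#' `spec@seed`.  With `epochs = 0` the untrained network is evaluated, which
#' is useful for output-contract checks.
#'
#' @param ds an [ExpressionDataset-class] with at least two classes and at
#'   least `spec@kernelSize` genes.
#' @param spec a [CNNSpec-class]; `spec@nClasses` must match the data.
#' @param ann optional [AnnotationMap-class] for functional gene ordering.
#' @param testFrac held-out fraction (default 0.2).
#' @return A [CnnResult-class] with per-epoch loss/accuracy/F1 traces.
#' @export
trainEvalCnn <- function(ds, spec, ann = NULL, testFrac = 0.2) {
  x <- exprsValues(ds)
  stopIfNot(ncol(x) >= spec@kernelSize,
            "feature count is smaller than the convolution kernel")
  order <- if (!is.null(ann)) sortGenesByFunction(geneIds(ds), ann)
           else geneIds(ds)
  x <- x[, order, drop = FALSE]
  y <- factor(unname(phenotype(ds)))
  stopIfNot(nlevels(y) >= 2L, "at least two phenotype classes required")
  stopIfNot(nlevels(y) == spec@nClasses,
            "spec@nClasses does not match the number of classes in the data")
  lv <- levels(y)
  yIdx <- as.integer(y)

  set.seed(spec@seed)
  testIdx <- stratifiedSplit(y, testFrac)
  trainIdx <- setdiff(seq_len(nrow(x)), testIdx)
  mu <- colMeans(x[trainIdx, , drop = FALSE])
  sdv <- apply(x[trainIdx, , drop = FALSE], 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  xTr <- xs[trainIdx, , drop = FALSE]; yTr <- yIdx[trainIdx]
  xTe <- xs[testIdx, , drop = FALSE]; yTe <- yIdx[testIdx]

  params <- initCnnParams(spec, ncol(xs))
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  C <- spec@nClasses
  hist <- list(); t <- 0L
  for (epoch in seq_len(spec@epochs)) {
    perm <- sample(length(trainIdx))
    starts <- seq(1L, length(perm), by = spec@batchSize)
    for (s in starts) {
      idx <- perm[s:min(s + spec@batchSize - 1L, length(perm))]
      if (length(idx) < 2L) next
      Y <- matrix(0, length(idx), C)
      Y[cbind(seq_along(idx), yTr[idx])] <- 1
      fw <- cnnForward(params, spec, xTr[idx, , drop = FALSE], training = TRUE)
      grads <- cnnBackward(params, spec, fw, Y)
      t <- t + 1L
      upd <- adamStep(state, params, grads, spec@learningRate, t)
      state <- upd$state; params <- upd$params
    }
    evTr <- cnnEvaluate(params, spec, xTr, yTr, lv)
    evTe <- cnnEvaluate(params, spec, xTe, yTe, lv)
    hist[[epoch]] <- data.frame(
      epoch = epoch, split = c("train", "test"),
      loss = c(evTr$loss, evTe$loss),
      accuracy = c(evTr$metrics["accuracy"], evTe$metrics["accuracy"]),
      f1 = c(evTr$metrics["f1"], evTe$metrics["f1"]))
  }
  evTr <- cnnEvaluate(params, spec, xTr, yTr, lv)
  evTe <- cnnEvaluate(params, spec, xTe, yTe, lv)
  new("CnnResult", spec = spec,
      history = if (length(hist)) do.call(rbind, hist)
                else data.frame(epoch = integer(0), split = character(0),
                                loss = numeric(0), accuracy = numeric(0),
                                f1 = numeric(0)),
      trainMetrics = c(loss = evTr$loss, evTr$metrics),
      testMetrics = c(loss = evTe$loss, evTe$metrics),
      testProbabilities = evTe$probs, geneOrder = order)
}
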