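## Repeated stratified 80/20 Monte-Carlo cross-validation with decision trees
## and Gaussian naive Bayes, plus confusion-matrix metrics.  "10-fold cross
## validation by splitting the data randomly into 80-20% in each fold" is
## read as 10 repeated random 80/20 splits, since classic 10-fold would imply
## 90/10 splits.

#' Metrics of a confusion matrix
#'
#' Rows are true classes, columns predicted classes.  Accuracy is
#' trace/total; precision and recall are macro-averaged over classes, with a
#' class contributing 0 when it has no predicted (respectively true)
#' instances; F1 is the harmonic mean of macro precision and macro recall.
#'
#' @param confusion square non-negative integer matrix.
#' @return Named numeric vector: accuracy, precision, recall, f1.
#' @examples
#' computeMetrics(matrix(c(3, 2, 1, 4), 2))  # acc 0.7, macro P 0.7
#' @export
computeMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopIfNot(nrow(confusion) > 0L, "empty confusion matrix")
  stopIfNot(nrow(confusion) == ncol(confusion), "confusion matrix must be square")
  stopIfNot(all(confusion >= 0) && all(confusion == round(confusion)),
            "confusion matrix must hold non-negative integer counts")
  total <- sum(confusion)
  stopIfNot(total > 0, "confusion matrix has no observations")
  tp <- diag(confusion)
  predTot <- colSums(confusion)
  trueTot <- rowSums(confusion)
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(trueTot > 0, tp / trueTot, 0)
  mp <- mean(prec); mr <- mean(rec)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  c(accuracy = sum(tp) / total, precision = mp, recall = mr, f1 = f1)
}

## stratified train/test split; classes with a single member stay in training
stratifiedSplit <- function(y, testFrac) {
  testIdx <- integer(0)
  for (lv in unique(y)) {
    idx <- which(y == lv)
    if (length(idx) < 2L) {
      warning("class ", lv, " has a single member; kept in training",
              call. = FALSE)
      next
    }
    nTest <- max(1L, round(testFrac * length(idx)))
    nTest <- min(nTest, length(idx) - 1L)   # at least one training member
    testIdx <- c(testIdx, sample(idx, nTest))
  }
  sort(testIdx)
}

confusionCounts <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

fitPredict <- function(model, xTrain, yTrain, xTest) {
  df <- as.data.frame(xTrain)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  dfTest <- as.data.frame(xTest)
  colnames(dfTest) <- colnames(df)
  if (model == "decision_tree") {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = yTrain),
                        method = "class")
    as.character(predict(fit, dfTest, type = "class"))
  } else {
    keep <- vapply(df, function(col) sd(col) > 0, logical(1))
    if (!any(keep)) keep[1L] <- TRUE
    fit <- e1071::naiveBayes(df[, keep, drop = FALSE], yTrain)
    as.character(predict(fit, dfTest[, keep, drop = FALSE]))
  }
}

#' Repeated cross-validated evaluation of a probabilistic classifier
#'
#' `reps` independent stratified random splits with `testFrac` of each class
#' held out (Monte-Carlo cross-validation); the model is retrained per split
#' and mean metrics are reported together with the per-split values.
#'
#' @param ds an [ExpressionDataset-class] with at least two classes.
#' @param model `"decision_tree"` (rpart) or `"naive_bayes"` (Gaussian,
#'   e1071; zero-variance features are dropped per split).
#' @param reps number of repetitions (default 10).
#' @param testFrac held-out fraction in (0,1) (default 0.2).
#' @param seed integer seed controlling the split sequence.
#' @return A [MetricsTable-class].
#' @export
evaluateProbabilistic <- function(ds, model = c("decision_tree", "naive_bayes"),
                                  reps = 10L, testFrac = 0.2, seed = 1L) {
  model <- match.arg(model)
  stopIfNot(reps >= 1L, "reps must be >= 1")
  stopIfNot(testFrac > 0 && testFrac < 1, "testFrac must lie in (0,1)")
  x <- exprsValues(ds)
  y <- factor(unname(phenotype(ds)))
  if (nlevels(y) < 2L)
    stop("evaluation requires at least two phenotype classes", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    testIdx <- stratifiedSplit(y, testFrac)
    pred <- fitPredict(model, x[-testIdx, , drop = FALSE], droplevels(y[-testIdx]),
                       x[testIdx, , drop = FALSE])
    cm <- confusionCounts(as.character(y[testIdx]), pred, levels(y))
    rows[[r]] <- as.list(computeMetrics(unclass(cm)))
  }
  folds <- do.call(rbind, lapply(rows, as.data.frame))
  new("MetricsTable", model = model, folds = folds,
      means = colMeans(as.matrix(folds)),
      nSamples = nrow(x), nFeatures = ncol(x))
}

#' Compare curated against full cohorts under cross-validation
#'
#' Runs the full dataset and its dominant-cycle curation through
#' [evaluateProbabilistic()].  Under the default `"within_split"` protocol
#' the curation is recomputed on the training rows of every split and the
#' model is tested on untouched held-out rows, so cohort selection never sees
#' test data; `"global"` curates once on the whole dataset and evaluates the
#' curated matrix by ordinary cross-validation (the protocol behind
#' headline-style comparisons, at the price of selection leakage).
#'
#' @param ds an [ExpressionDataset-class].
#' @param model,reps,testFrac,seed as in [evaluateProbabilistic()].
#' @param protocol `"within_split"` (default) or `"global"`.
#' @param ... curation arguments forwarded to [curateCohorts()].
#' @return A list with MetricsTable elements `full` and `curated`.
#' @export
compareCuratedVsFull <- function(ds, model = "decision_tree", reps = 10L,
                                 testFrac = 0.2, seed = 1L,
                                 protocol = c("within_split", "global"), ...) {
  protocol <- match.arg(protocol)
  full <- evaluateProbabilistic(ds, model, reps, testFrac, seed)
  if (protocol == "global") {
    cur <- curateCohorts(ds, ...)
    curDs <- curatedDataset(cur)
    stopIfNot(!is.null(curDs), "curation selected no cohorts")
    curated <- evaluateProbabilistic(curDs, model, reps, testFrac, seed)
    return(list(full = full, curated = curated))
  }
  x <- exprsValues(ds)
  y <- factor(unname(phenotype(ds)))
  set.seed(as.integer(seed))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    testIdx <- stratifiedSplit(y, testFrac)
    trainDs <- ds[, cohortIds(ds)[-testIdx]]
    cur <- suppressWarnings(curateCohorts(trainDs, ...))
    keep <- selectedCohorts(cur)
    if (length(keep) < 4L || nlevels(droplevels(
          factor(phenotype(ds)[keep]))) < 2L) {
      keep <- cohortIds(trainDs)   # degenerate curation: fall back to full
    }
    xi <- x[keep, , drop = FALSE]
    yi <- droplevels(factor(phenotype(ds)[keep]))
    pred <- fitPredict(model, xi, yi, x[testIdx, , drop = FALSE])
    cm <- confusionCounts(as.character(y[testIdx]), pred, levels(y))
    rows[[r]] <- as.list(computeMetrics(unclass(cm)))
  }
  folds <- do.call(rbind, lapply(rows, as.data.frame))
  curated <- new("MetricsTable", model = model, folds = folds,
                 means = colMeans(as.matrix(folds)),
                 nSamples = nrow(x), nFeatures = ncol(x))
  list(full = full, curated = curated)
}

#' Order genes by functional annotation
#'
#' Stable sort on each gene's lexicographically smallest annotation term, so
#' genes sharing a term become contiguous blocks and genes with equal keys
#' keep their input order.
#'
#' @param geneIds character vector.
#' @param ann an [AnnotationMap-class]; missing genes are treated as carrying
#'   the reserved term.
#' @return A permutation of `geneIds`.
#' @export
sortGenesByFunction <- function(geneIds, ann) {
  ann <- completeAnnotations(ann, geneIds, warn = FALSE)
  key <- vapply(annotationTerms(ann, geneIds),
                function(t) sort(t)[1L], character(1))
  geneIds[order(key)]            # order() is a stable sort
}
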