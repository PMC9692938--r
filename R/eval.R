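## Pluggable classifier roster and the confusion-matrix metric suite.
## Classifier internals are deliberately delegated to rpart, e1071,
## class, randomForest and MASS; everything metric is computed here.

#' Specify a classifier from the supported roster
#'
#' Families: `decision_tree` (rpart), `svm` (e1071, RBF kernel default),
#' `knn` (class::knn, `k` neighbors, default 1), `ensemble`
#' (randomForest), `naive_bayes` (e1071) and `discriminant` (MASS linear
#' discriminant analysis). Extra arguments are passed through to the
#' underlying fit and echoed in reports for reproducibility.
#'
#' @param family one of the roster names above
#' @param ... hyperparameters forwarded to the backend
#' @param seed integer seed applied around stochastic fits
#' @return a list of class `"ClassifierSpec"`
#' @examples
#' classifierSpec("knn", k = 3)
#' @export
classifierSpec <- function(family = c("knn", "decision_tree", "svm",
                                      "ensemble", "naive_bayes",
                                      "discriminant"),
                           ..., seed = 1L) {
  family <- match.arg(family)
  spec <- list(family = family, hyper = list(...), seed = as.integer(seed))
  class(spec) <- "ClassifierSpec"
  spec
}

# fit + predict in one step; knn is lazy so both phases live together
.fit_predict <- function(spec, Xtr, ytr, Xte) {
  fam <- spec$family
  hp <- spec$hyper
  if (fam == "knn") {
    k <- if (is.null(hp$k)) 1L else as.integer(hp$k)
    return(.with_seed(spec$seed,
                      class::knn(Xtr, Xte, cl = ytr, k = k)))
  }
  dtr <- data.frame(Xtr, check.names = FALSE)
  names(dtr) <- paste0("V", seq_len(ncol(Xtr)))
  dtr$.label <- ytr
  dte <- data.frame(Xte, check.names = FALSE)
  names(dte) <- paste0("V", seq_len(ncol(Xte)))
  .with_seed(spec$seed, switch(fam,
    decision_tree = {
      fit <- do.call(rpart::rpart,
                     c(list(.label ~ ., data = dtr, method = "class"), hp))
      factor(predict(fit, dte, type = "class"), levels = levels(ytr))
    },
    svm = {
      fit <- do.call(e1071::svm, c(list(.label ~ ., data = dtr), hp))
      factor(predict(fit, dte), levels = levels(ytr))
    },
    ensemble = {
      fit <- do.call(randomForest::randomForest,
                     c(list(.label ~ ., data = dtr), hp))
      factor(predict(fit, dte), levels = levels(ytr))
    },
    naive_bayes = {
      fit <- do.call(e1071::naiveBayes, c(list(.label ~ ., data = dtr), hp))
      factor(predict(fit, dte), levels = levels(ytr))
    },
    discriminant = {
      fit <- do.call(MASS::lda, c(list(.label ~ ., data = dtr), hp))
      factor(predict(fit, dte)$class, levels = levels(ytr))
    }))
}

#' Confusion matrix from true and predicted labels
#'
#' @param yTrue,yPred integer codes in `[0, C)` or factors over the same
#'   levels, equal length
#' @param C number of classes; inferred from factor levels when missing
#' @return C x C integer matrix, rows = true class, columns = predicted
#' @export
confusion <- function(yTrue, yPred, C = NULL) {
  if (length(yTrue) != length(yPred)) stop("label vectors must align")
  if (is.factor(yTrue) || is.factor(yPred)) {
    lev <- union(levels(as.factor(yTrue)), levels(as.factor(yPred)))
    yTrue <- as.integer(factor(yTrue, levels = lev)) - 1L
    yPred <- as.integer(factor(yPred, levels = lev)) - 1L
    if (is.null(C)) C <- length(lev)
  }
  if (is.null(C)) C <- max(yTrue, yPred) + 1L
  if (any(yTrue < 0L | yTrue >= C | yPred < 0L | yPred >= C))
    stop("labels out of range [0, C)")
  m <- matrix(0L, C, C)
  for (i in seq_along(yTrue))
    m[yTrue[i] + 1L, yPred[i] + 1L] <- m[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  m
}

#' One-vs-rest binary counts for a class
#'
#' @param mat confusion matrix (rows = true, columns = predicted)
#' @param c class index, 1-based
#' @return list with `tp`, `tn`, `fp`, `fn`
#' @export
binaryCounts <- function(mat, c) {
  C <- nrow(mat)
  if (c < 1L || c > C) stop("invalid class index")
  tp <- mat[c, c]
  fn <- sum(mat[c, ]) - tp
  fp <- sum(mat[, c]) - tp
  tn <- sum(mat) - tp - fn - fp
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# a rate with 0/0 defined as 0; flags records which rates degenerated
.rate <- function(num, den, name, flags) {
  if (den == 0) {
    flags$hit <- c(flags$hit, name)
    return(0)
  }
  num / den
}

#' Binary metric bundle from TP/TN/FP/FN counts
#'
#' Computes accuracy, sensitivity (TPR), specificity (TNR), precision (PPV),
#' negative predictive value (NPV), F1, misclassification rate and the
#' Matthews correlation coefficient
#' \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' Any rate with a zero denominator is reported as 0 and flagged.
#'
#' @param b list with `tp`, `tn`, `fp`, `fn` (see [binaryCounts()])
#' @return named numeric vector with attribute `"zeroDenominator"` listing
#'   flagged rates
#' @export
metricsFromCounts <- function(b) {
  tp <- b$tp; tn <- b$tn; fp <- b$fp; fn <- b$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty counts")
  flags <- new.env(parent = emptyenv()); flags$hit <- character(0)
  acc <- (tp + tn) / total
  tpr <- .rate(tp, tp + fn, "tpr", flags)
  tnr <- .rate(tn, tn + fp, "tnr", flags)
  ppv <- .rate(tp, tp + fp, "ppv", flags)
  npv <- .rate(tn, tn + fn, "npv", flags)
  f1 <- .rate(2 * tp, 2 * tp + fp + fn, "f1", flags)
  mr <- (fp + fn) / total
  mccDen <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  mcc <- .rate(tp * tn - fp * fn, mccDen, "mcc", flags)
  out <- c(acc = acc, tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
           f1 = f1, mr = mr, mcc = mcc)
  attr(out, "zeroDenominator") <- flags$hit
  out
}

#' Macro-averaged multiclass metric report
#'
#' Each class is reduced one-vs-rest to binary counts, the binary metric
#' bundle is computed per class, and rate metrics are macro-averaged.
#' Overall accuracy comes from the full-matrix trace and
#' `mr = 1 - acc`, so the pair is always consistent.
#'
#' @param mat confusion matrix (rows = true, columns = predicted), C >= 2
#' @return a \linkS4class{MetricReport}
#' @export
macroMetrics <- function(mat) {
  C <- nrow(mat)
  if (C < 2L || sum(mat) == 0) stop("need a non-empty matrix with C >= 2")
  per <- t(vapply(seq_len(C),
                  function(c) metricsFromCounts(binaryCounts(mat, c)),
                  numeric(8)))
  colnames(per) <- c("acc", "tpr", "tnr", "ppv", "npv", "f1", "mr", "mcc")
  rownames(per) <- rownames(mat) %||% paste0("class", seq_len(C) - 1L)
  flags <- unlist(lapply(seq_len(C), function(c)
    attr(metricsFromCounts(binaryCounts(mat, c)), "zeroDenominator")))
  overall <- colMeans(per)
  overall[["acc"]] <- sum(diag(mat)) / sum(mat)
  overall[["mr"]] <- 1 - overall[["acc"]]
  storage.mode(mat) <- "integer"
  new("MetricReport", overall = overall, perClass = per, confusion = mat,
      zeroDenominatorFlags = unique(flags %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (", nrow(object@confusion), "classes,",
      sum(object@confusion), "samples )\n")
  print(round(object@overall, 4))
  if (length(object@zeroDenominatorFlags))
    cat("zero-denominator rates reported as 0:",
        paste(object@zeroDenominatorFlags, collapse = ", "), "\n")
})

#' Fit on a training table, evaluate on a test table
#'
#' @param spec a [classifierSpec()]
#' @param trainTable,testTable labeled \linkS4class{FeatureTable}s sharing
#'   features and label space
#' @return a \linkS4class{MetricReport}
#' @export
evaluateClassifier <- function(spec, trainTable, testTable) {
  stopifnot(inherits(spec, "ClassifierSpec"),
            is(trainTable, "FeatureTable"), is(testTable, "FeatureTable"))
  ytr <- sampleLabels(trainTable)
  yte <- sampleLabels(testTable)
  if (is.null(ytr) || is.null(yte)) stop("both tables must be labeled")
  if (!identical(featureIds(trainTable), featureIds(testTable)))
    stop("train and test tables must share features")
  lev <- union(levels(ytr), levels(yte))
  ytr <- factor(ytr, levels = lev)
  yte <- factor(yte, levels = lev)
  pred <- .fit_predict(spec, featureMatrix(trainTable), ytr,
                       featureMatrix(testTable))
  macroMetrics(confusion(yte, pred, C = length(lev)))
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin over folds
.stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < folds)
      stop("class '", lv, "' has fewer samples than folds")
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated misclassification error
#'
#' Restricts the table to `subset`, deals samples of each class round-robin
#' into `folds` folds after a seeded shuffle, and averages the per-fold
#' misclassification rates of the classifier.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @param subset integer feature indices to use (default: all)
#' @param spec a [classifierSpec()]
#' @param folds number of folds, >= 2; every class must have at least
#'   `folds` samples
#' @param seed seed for the fold shuffle
#' @param foldAssign optional precomputed fold assignment vector (overrides
#'   `seed`)
#' @return mean misclassification rate in \eqn{[0, 1]}
#' @export
crossValError <- function(table, subset = NULL, spec = classifierSpec("knn"),
                          folds = 5L, seed = 1L, foldAssign = NULL) {
  stopifnot(is(table, "FeatureTable"))
  y <- sampleLabels(table)
  if (is.null(y)) stop("cross-validation needs labels")
  if (folds < 2L) stop("folds must be >= 2")
  X <- featureMatrix(table)
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  if (is.null(foldAssign))
    foldAssign <- .with_seed(seed, .stratified_folds(y, folds))
  errs <- vapply(seq_len(max(foldAssign)), function(f) {
    te <- foldAssign == f
    pred <- .fit_predict(spec, X[!te, , drop = FALSE], y[!te],
                         X[te, , drop = FALSE])
    mean(pred != y[te])
  }, numeric(1))
  mean(errs)
}

#' Serialize a MetricReport to JSON
#'
#' Field names mirror the standard abbreviations (ACC, TPR, TNR, PPV, NPV,
#' F1, MR, MCC); the confusion matrix is included as an integer grid.
#'
#' @param report a \linkS4class{MetricReport}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMetricReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  up <- function(v) stats::setNames(as.list(v), toupper(names(v)))
  jsonlite::write_json(
    list(overall = up(report@overall),
         per_class = apply(report@perClass, 1L, up, simplify = FALSE),
         confusion = unname(report@confusion),
         zero_denominator_rates = report@zeroDenominatorFlags),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
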