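test_that("confusion matrices tally true/predicted pairs", {
  expect_equal(confusion(rep(0:1, each = 5), rep(0:1, each = 5), 2),
               matrix(c(5L, 0L, 0L, 5L), 2))
  m <- confusion(c(0, 1, 1, 2), rep(0, 4), 3)
  expect_equal(sum(m[, 1]), 4L)
  expect_equal(sum(m[, -1]), 0L)
  set.seed(6)
  yt <- sample(0:2, 50, replace = TRUE)
  yp <- sample(0:2, 50, replace = TRUE)
  m2 <- confusion(yt, yp, 3)
  for (i in 0:2) for (j in 0:2)
    expect_equal(m2[i + 1, j + 1], sum(yt == i & yp == j))
  expect_error(confusion(c(0, 3), c(0, 1), 2), "out of range")
})

test_that("one-vs-rest reduction preserves totals", {
  m <- matrix(c(3, 2, 1, 4), 2, byrow = TRUE)
  b <- binaryCounts(m, 1)
  expect_equal(b, list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(b$tp + b$tn + b$fp + b$fn, sum(m))
  perfect <- binaryCounts(matrix(c(5, 0, 0, 5), 2), 1)
  expect_equal(perfect, list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_error(binaryCounts(m, 3), "invalid class")
})

test_that("metric algebra matches an independent re-derivation", {
  perfect <- metricsFromCounts(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(perfect[c("acc", "f1", "mcc", "mr")]), c(1, 1, 1, 0))
  chance <- metricsFromCounts(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(chance[["mcc"]], 0)
  one <- metricsFromCounts(list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(one[["acc"]], 0.7)
  expect_equal(one[["tpr"]], 0.6)
  expect_equal(one[["ppv"]], 0.75)
  expect_equal(one[["f1"]], 2 * 3 / 9)
  expect_equal(one[["mr"]], 0.3)
  set.seed(10)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(rpois(4, 8), c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cts)) == 0) next
    got <- metricsFromCounts(cts)
    want <- oracle_metrics(cts$tp, cts$tn, cts$fp, cts$fn)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
    expect_equal(got[["acc"]] + got[["mr"]], 1, tolerance = 1e-12)
    expect_gte(got[["mcc"]], -1)
    expect_lte(got[["mcc"]], 1)
    # F1 is the harmonic mean of PPV and TPR when both are defined
    if (got[["ppv"]] + got[["tpr"]] > 0 && cts$tp > 0)
      expect_equal(got[["f1"]],
                   2 * got[["ppv"]] * got[["tpr"]] /
                     (got[["ppv"]] + got[["tpr"]]), tolerance = 1e-12)
  }
  # zero-denominator rates are 0 and flagged, never NaN
  none <- metricsFromCounts(list(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_equal(none[["ppv"]], 0)
  expect_true("ppv" %in% attr(none, "zeroDenominator"))
  expect_false(anyNA(none))
  expect_error(metricsFromCounts(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("macro metrics aggregate per-class one-vs-rest reports", {
  perfect <- macroMetrics(diag(c(4L, 5L, 6L)))
  expect_equal(unname(perfect@overall[c("acc", "tpr", "f1", "mcc")]),
               rep(1, 4))
  expect_equal(perfect@overall[["mr"]], 0)
  set.seed(12)
  m <- matrix(rpois(9, 10), 3)
  rep <- macroMetrics(m)
  per <- t(vapply(1:3, function(c) {
    b <- binaryCounts(m, c)
    oracle_metrics(b$tp, b$tn, b$fp, b$fn)
  }, numeric(8)))
  for (nm in c("tpr", "tnr", "ppv", "npv", "f1", "mcc"))
    expect_equal(rep@overall[[nm]], mean(per[, nm]), tolerance = 1e-12)
  expect_equal(rep@overall[["acc"]], sum(diag(m)) / sum(m))
  expect_equal(rep@overall[["acc"]] + rep@overall[["mr"]], 1,
               tolerance = 1e-12)
  # symmetric confusions: per-class metrics equal the macro values
  sym <- macroMetrics(matrix(c(8L, 2L, 2L, 8L), 2))
  expect_equal(unname(sym@perClass[1, ]), unname(sym@perClass[2, ]))
  expect_error(macroMetrics(matrix(0L, 2, 2)), "non-empty")
})

test_that("every roster family separates an easy planted problem", {
  syn <- makeFeatureTable(nSamples = 120, nFeatures = 10, nInformative = 4,
                          nRedundant = 0, nClasses = 2, effectSize = 6,
                          seed = 21)
  sp <- stratifiedSplit(sampleLabels(syn$table), seed = 4)
  tr <- subsetFeatures(syn$table, samples = sp$train)
  te <- subsetFeatures(syn$table, samples = sp$test)
  for (fam in c("knn", "decision_tree", "svm", "ensemble", "naive_bayes",
                "discriminant")) {
    rep <- evaluateClassifier(classifierSpec(fam, seed = 7), tr, te)
    expect_gte(rep@overall[["acc"]], 0.95)
  }
  # shuffled labels give chance-level accuracy
  set.seed(31)
  shuf <- FeatureTable(featureMatrix(syn$table),
                       y = sample(sampleLabels(syn$table)))
  trS <- subsetFeatures(shuf, samples = sp$train)
  teS <- subsetFeatures(shuf, samples = sp$test)
  repS <- evaluateClassifier(classifierSpec("knn", seed = 7), trS, teS)
  expect_lt(repS@overall[["acc"]], 0.80)
  # determinism of a stochastic family
  r1 <- evaluateClassifier(classifierSpec("ensemble", seed = 9), tr, te)
  r2 <- evaluateClassifier(classifierSpec("ensemble", seed = 9), tr, te)
  expect_identical(r1@overall, r2@overall)
})

test_that("cross-validation error separates signal from noise subsets", {
  syn <- makeFeatureTable(nSamples = 150, nFeatures = 20, nInformative = 4,
                          nRedundant = 0, nClasses = 3, effectSize = 4,
                          seed = 15)
  noise <- setdiff(seq_len(20), c(syn$informative, syn$redundant))
  errInf <- crossValError(syn$table, syn$informative,
                          classifierSpec("knn"), seed = 3)
  errNoise <- crossValError(syn$table, noise[1:4],
                            classifierSpec("knn"), seed = 3)
  expect_lt(errInf, 0.05)
  expect_gt(errNoise, 1 - 1 / 3 - 0.15)   # about chance for 3 classes
  expect_error(crossValError(syn$table, folds = 1), "folds")
  tiny <- FeatureTable(matrix(rnorm(8), 4, 2), y = c(0, 0, 1, 1))
  expect_error(crossValError(tiny, spec = classifierSpec("knn"), folds = 3),
               "fewer samples than folds")
})

test_that("metric reports serialize with uppercase field names", {
  rep <- macroMetrics(matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE))
  f <- tempfile(fileext = ".json")
  writeMetricReport(rep, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$overall$ACC, rep@overall[["acc"]])
  expect_equal(j$overall$MCC, rep@overall[["mcc"]])
  expect_equal(unname(as.matrix(j$confusion)), unname(rep@confusion),
               ignore_attr = TRUE)
})
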