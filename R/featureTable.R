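#' Construct a FeatureTable
#'
#' @param X numeric matrix, one row per sample, one column per feature.
#'   A data.frame of numeric columns is accepted and coerced.
#' @param y optional class labels (factor, character or integer), one per
#'   sample. Omit (or pass `NULL`) for an unlabeled table.
#' @param featureIds feature names; defaults to the column names of `X`, or
#'   `f1..fF` when absent.
#' @return a \linkS4class{FeatureTable}
#' @examples
#' ft <- FeatureTable(matrix(rnorm(20), 5, 4), y = c(0, 0, 1, 1, 1))
#' nFeatures(ft)
#' @export
FeatureTable <- function(X, y = NULL, featureIds = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(featureIds)) {
    featureIds <- colnames(X)
    if (is.null(featureIds)) featureIds <- paste0("f", seq_len(ncol(X)))
  }
  colnames(X) <- featureIds
  y <- if (is.null(y)) factor(character(0)) else as.factor(y)
  new("FeatureTable", X = X, y = y, featureIds = as.character(featureIds))
}

#' @rdname FeatureTable-class
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@X)

#' @rdname FeatureTable-class
#' @export
setMethod("sampleLabels", "FeatureTable", function(x) {
  if (length(x@y) == 0L) NULL else x@y
})

#' @rdname FeatureTable-class
#' @export
setMethod("featureIds", "FeatureTable", function(x) x@featureIds)

#' @rdname FeatureTable-class
#' @export
setMethod("nSamples", "FeatureTable", function(x) nrow(x@X))

#' @rdname FeatureTable-class
#' @export
setMethod("nFeatures", "FeatureTable", function(x) ncol(x@X))

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@X), "samples x", ncol(object@X),
      "features\n")
  if (length(object@y) > 0L) {
    tab <- table(object@y)
    cat("labels:", paste0(names(tab), " (", as.integer(tab), ")",
                          collapse = ", "), "\n")
  } else {
    cat("labels: none\n")
  }
})

#' Restrict a FeatureTable to a subset of features and/or samples
#'
#' @param table a \linkS4class{FeatureTable}
#' @param features integer or character vector of features to keep
#' @param samples integer vector of sample rows to keep
#' @return a \linkS4class{FeatureTable}
#' @export
subsetFeatures <- function(table, features = NULL, samples = NULL) {
  stopifnot(is(table, "FeatureTable"))
  X <- table@X
  y <- sampleLabels(table)
  if (!is.null(samples)) {
    X <- X[samples, , drop = FALSE]
    if (!is.null(y)) y <- y[samples]
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, table@featureIds)
    X <- X[, features, drop = FALSE]
  }
  FeatureTable(X, y = if (is.null(y)) NULL else droplevels(y))
}

#' Read a feature table from delimited text
#'
#' Expected layout: a header row; the first column holds sample identifiers;
#' a column named `label` (if present) holds class labels; all remaining
#' columns are numeric features. Missing values are rejected.
#'
#' @param path CSV file path
#' @param sep field separator, default comma
#' @return a \linkS4class{FeatureTable}
#' @export
readFeatureTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an id column and >= 1 feature")
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  y <- NULL
  if ("label" %in% names(df)) {
    y <- df[["label"]]
    df <- df[, setdiff(names(df), "label"), drop = FALSE]
  }
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("all feature columns must be numeric")
  if (anyNA(X)) stop("missing values are not allowed in feature tables")
  ft <- FeatureTable(X, y = y, featureIds = colnames(df))
  rownames(ft@X) <- as.character(ids)
  ft
}

#' Write a feature table as delimited text
#'
#' Inverse of [readFeatureTable()]: first column `id`, then a `label` column
#' when the table is labeled, then the feature columns.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path output CSV path
#' @param sep field separator
#' @return `path`, invisibly
#' @export
writeFeatureTable <- function(table, path, sep = ",") {
  stopifnot(is(table, "FeatureTable"))
  ids <- rownames(table@X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(table@X)))
  df <- data.frame(id = ids, check.names = FALSE)
  y <- sampleLabels(table)
  if (!is.null(y)) df$label <- as.character(y)
  df <- cbind(df, as.data.frame(table@X, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
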