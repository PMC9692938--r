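#' @import methods
NULL

#' FeatureTable: samples-by-features matrix with optional class labels
#'
#' The central data container of the package: a numeric matrix with one row
#' per sample and one column per feature, optionally carrying a factor of
#' class labels. All selection, relevance and classification machinery
#' operates on this class.
#'
#' @slot X numeric matrix, \code{n_samples x n_features}; all entries finite.
#' @slot y factor of length \code{n_samples}, or a zero-length factor when
#'   the table is unlabeled.
#' @slot featureIds character vector of feature identifiers, one per column.
#'
#' @seealso [FeatureTable()] for the user-facing constructor,
#'   [featureMatrix()], [sampleLabels()], [featureIds()] for accessors.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(X = "matrix", y = "factor", featureIds = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@X)) msg <- c(msg, "X must be a numeric matrix")
    if (nrow(object@X) < 1L) msg <- c(msg, "X must have at least one sample")
    if (ncol(object@X) < 1L) msg <- c(msg, "X must have at least one feature")
    if (is.numeric(object@X) && !all(is.finite(object@X)))
      msg <- c(msg, "all entries of X must be finite")
    if (length(object@y) > 0L && length(object@y) != nrow(object@X))
      msg <- c(msg, "length(y) must equal nrow(X)")
    if (length(object@featureIds) != ncol(object@X))
      msg <- c(msg, "featureIds must have one entry per feature column")
    if (anyDuplicated(object@featureIds))
      msg <- c(msg, "featureIds must be unique")
    if (is.null(msg)) TRUE else msg
  }
)

#' RelevanceProfile: symmetrical-uncertainty relevance and redundancy
#'
#' Holds the feature-class relevance vector (SU_FC) and the feature-feature
#' redundancy matrix (SU_FF) computed from a labeled [FeatureTable]. These
#' feed the heuristic desirability values used by the ant colony search.
#'
#' @slot suFC numeric vector of length \code{n_features}, each entry the
#'   symmetrical uncertainty between a feature and the class labels, in
#'   \eqn{[0, 1]}.
#' @slot suFF symmetric numeric matrix of pairwise feature-feature
#'   symmetrical uncertainties, entries in \eqn{[0, 1]}.
#' @slot featureIds character vector naming the features.
#'
#' @seealso [relevanceProfile()], [heuristicFC()], [heuristicFF()]
#' @exportClass RelevanceProfile
setClass("RelevanceProfile",
  representation(suFC = "numeric", suFF = "matrix", featureIds = "character"),
  validity = function(object) {
    msg <- NULL
    tol <- 1e-12
    f <- length(object@suFC)
    if (!all(dim(object@suFF) == c(f, f)))
      msg <- c(msg, "suFF must be an F x F matrix matching length(suFC)")
    rng <- range(c(object@suFC, object@suFF))
    if (rng[1] < -tol || rng[2] > 1 + tol)
      msg <- c(msg, "all SU values must lie in [0, 1]")
    if (max(abs(object@suFF - t(object@suFF))) > tol)
      msg <- c(msg, "suFF must be symmetric")
    if (length(object@featureIds) != f)
      msg <- c(msg, "featureIds must match the number of features")
    if (is.null(msg)) TRUE else msg
  }
)

#' SelectionResult: outcome of an ant colony feature-selection run
#'
#' @slot bestSubset integer vector of selected feature indices (1-based in R;
#'   serialized 0-based by [writeSelectionResult()]).
#' @slot bestScore best subset quality found over the whole run.
#' @slot history numeric vector, the global-best score after each iteration
#'   (non-decreasing by construction).
#' @slot finalTau pheromone vector at termination, strictly positive.
#' @slot seed integer seed that reproduces the run.
#' @slot config list echo of the [acoConfig()] used.
#'
#' @seealso [runACO()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(bestSubset = "integer", bestScore = "numeric",
                 history = "numeric", finalTau = "numeric",
                 seed = "integer", config = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@bestSubset))
      msg <- c(msg, "bestSubset must not contain duplicate indices")
    if (length(object@history) > 0L &&
        abs(max(object@history) - object@bestScore) > 1e-9)
      msg <- c(msg, "bestScore must equal the maximum of history")
    if (any(object@finalTau <= 0))
      msg <- c(msg, "pheromone vector must stay strictly positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' AutoencoderModel: weights of a single-hidden-layer auto-encoder
#'
#' Encoder \eqn{z = h^{(1)}(W_1 x + b_1)} and decoder
#' \eqn{\hat x = h^{(2)}(W_2 z + b_2)}, trained by full-batch gradient
#' descent on the mean squared reconstruction error.
#'
#' @slot W1 numeric matrix \code{hiddenDim x inputDim}.
#' @slot b1 numeric vector of length \code{hiddenDim}.
#' @slot W2 numeric matrix \code{inputDim x hiddenDim}.
#' @slot b2 numeric vector of length \code{inputDim}.
#' @slot config list echo of the [aeConfig()] used for training.
#' @slot costHistory numeric vector of the cost after each epoch.
#'
#' @seealso [trainAutoencoder()], [aeEncode()], [aeDecode()]
#' @exportClass AutoencoderModel
setClass("AutoencoderModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", config = "list", costHistory = "numeric"),
  validity = function(object) {
    msg <- NULL
    d1 <- nrow(object@W1); dx <- ncol(object@W1)
    if (length(object@b1) != d1) msg <- c(msg, "b1 length must match nrow(W1)")
    if (!all(dim(object@W2) == c(dx, d1)))
      msg <- c(msg, "W2 must be inputDim x hiddenDim")
    if (length(object@b2) != dx) msg <- c(msg, "b2 length must match nrow(W2)")
    ok <- all(is.finite(object@W1)) && all(is.finite(object@b1)) &&
      all(is.finite(object@W2)) && all(is.finite(object@b2))
    if (!ok) msg <- c(msg, "all parameters must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' MetricReport: multiclass confusion-matrix metric bundle
#'
#' Per-class one-vs-rest metrics and their macro averages, together with the
#' underlying confusion matrix. Overall accuracy is computed from the matrix
#' trace and the misclassification rate is its complement, so
#' \code{ACC + MR = 1} holds on every report.
#'
#' @slot overall named numeric vector with entries \code{acc, tpr, tnr, ppv,
#'   npv, f1, mr, mcc}.
#' @slot perClass numeric matrix, one row per class, same metric columns.
#' @slot confusion integer confusion matrix (rows = true, columns = predicted).
#' @slot zeroDenominatorFlags character vector naming any per-class rates
#'   whose denominator was zero (the rate is reported as 0).
#'
#' @seealso [macroMetrics()], [evaluateClassifier()]
#' @exportClass MetricReport
setClass("MetricReport",
  representation(overall = "numeric", perClass = "matrix",
                 confusion = "matrix", zeroDenominatorFlags = "character"),
  validity = function(object) {
    msg <- NULL
    need <- c("acc", "tpr", "tnr", "ppv", "npv", "f1", "mr", "mcc")
    if (!all(need %in% names(object@overall)))
      msg <- c(msg, "overall must contain the full metric set")
    if (all(c("acc", "mr") %in% names(object@overall)) &&
        abs(object@overall[["acc"]] + object@overall[["mr"]] - 1) > 1e-12)
      msg <- c(msg, "acc + mr must equal 1")
    if (any(object@confusion < 0))
      msg <- c(msg, "confusion counts must be non-negative")
    if (is.null(msg)) TRUE else msg
  }
)
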