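## Entropy / mutual-information / symmetrical-uncertainty machinery.
## All entropies are in bits (log base 2); probabilities are maximum-
## likelihood empirical counts with 0 * log(0) taken as 0.

#' Discretize a continuous feature vector into integer category codes
#'
#' Entropy-based relevance scores operate on discrete variables; continuous
#' features are binned first. Two strategies are offered: `equal_width`
#' splits the observed range into `nBins` equal intervals; `equal_frequency`
#' cuts at empirical quantiles so bins have near-equal occupancy. A constant
#' feature yields a single category under either strategy. Codes are 0-based.
#'
#' @param x numeric vector, all finite
#' @param nBins integer >= 2, number of bins
#' @param strategy `"equal_width"` or `"equal_frequency"`
#' @return integer vector of 0-based category codes with attribute
#'   `"cutPoints"` (the strictly increasing interior cut points used)
#' @examples
#' discretize(c(0, 5, 10), nBins = 2)           # 0 1 1
#' discretize(runif(100), nBins = 4, strategy = "equal_frequency")
#' @export
discretize <- function(x, nBins = 10L,
                       strategy = c("equal_width", "equal_frequency")) {
  strategy <- match.arg(strategy)
  if (length(x) < 1L) stop("cannot discretize an empty vector")
  if (!all(is.finite(x))) stop("x must be finite")
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) {              # degenerate range: one bin
    codes <- integer(length(x))
    attr(codes, "cutPoints") <- numeric(0)
    return(codes)
  }
  if (strategy == "equal_width") {
    width <- (rng[2] - rng[1]) / nBins
    cut <- rng[1] + width * seq_len(nBins - 1L)
  } else {
    qs <- stats::quantile(x, probs = seq_len(nBins - 1L) / nBins, names = FALSE)
    cut <- unique(qs)
    cut <- cut[cut > rng[1] & cut < rng[2]]
  }
  codes <- findInterval(x, cut)        # number of cut points <= x
  codes <- as.integer(codes)
  attr(codes, "cutPoints") <- cut
  codes
}

#' Discretize every feature column of a table
#'
#' @param table a \linkS4class{FeatureTable}
#' @inheritParams discretize
#' @return integer matrix of 0-based codes, same dimensions as the feature
#'   matrix
#' @export
discretizeTable <- function(table, nBins = 10L,
                            strategy = c("equal_width", "equal_frequency")) {
  stopifnot(is(table, "FeatureTable"))
  if (nSamples(table) < 1L) stop("empty table")
  strategy <- match.arg(strategy)
  X <- featureMatrix(table)
  codes <- vapply(seq_len(ncol(X)),
                  function(j) as.integer(discretize(X[, j], nBins, strategy)),
                  integer(nrow(X)))
  codes <- matrix(codes, nrow = nrow(X),
                  dimnames = list(NULL, featureIds(table)))
  codes
}

# empirical probabilities of a code vector
.emp_p <- function(codes) {
  as.vector(table(codes)) / length(codes)
}

#' Shannon entropy of a discrete sample, in bits
#'
#' \eqn{H(X) = -\sum_i p(x_i) \log_2 p(x_i)} with empirical
#' (count / n) probabilities.
#'
#' @param codes vector of category codes (any atomic type; values are used
#'   as categories)
#' @return entropy in bits, in \eqn{[0, \log_2 K]} for K observed categories
#' @examples
#' shannonEntropy(c(0, 1, 0, 1))  # 1 bit
#' @export
shannonEntropy <- function(codes) {
  if (length(codes) < 1L) stop("entropy of an empty sample is undefined")
  p <- .emp_p(codes)
  -sum(p * log2(p))
}

#' Joint entropy of two equally long discrete samples, in bits
#'
#' @param a,b category code vectors of equal length
#' @return \eqn{H(A, B)} in bits
#' @export
jointEntropy <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  shannonEntropy(paste(a, b, sep = "\r"))
}

#' Conditional entropy H(A | B), in bits
#'
#' Computed directly from the empirical joint and conditional probabilities;
#' equals \code{jointEntropy(a, b) - shannonEntropy(b)} by the chain rule.
#'
#' @inheritParams jointEntropy
#' @return \eqn{H(A \mid B) \ge 0} in bits
#' @export
conditionalEntropy <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  joint <- table(a, b) / length(a)
  pb <- colSums(joint)
  h <- 0
  for (j in seq_along(pb)) {
    pj <- joint[, j]
    pj <- pj[pj > 0]
    if (length(pj) > 0L) h <- h - sum(pj * log2(pj / pb[j]))
  }
  as.numeric(h)
}

#' Information factor (mutual information) between two discrete samples
#'
#' The information factor \eqn{I(A, B) = H(A) - H(A \mid B)}, in bits. Zero
#' when the samples are empirically independent; symmetric in its arguments.
#'
#' @inheritParams jointEntropy
#' @return mutual information in bits, \eqn{\ge 0} up to round-off
#' @export
informationFactor <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  shannonEntropy(a) - conditionalEntropy(a, b)
}

#' Symmetrical uncertainty between two discrete samples
#'
#' \eqn{SU(A, B) = 2 I(A, B) / (H(A) + H(B))}, a normalized mutual
#' information in \eqn{[0, 1]}: 1 for identical (non-constant) variables,
#' 0 for empirically independent ones. When both variables are constant the
#' ratio is 0/0; constants carry no information, so SU is defined as 0.
#'
#' @inheritParams jointEntropy
#' @return SU in \eqn{[0, 1]}
#' @examples
#' x <- rep(0:1, 50)
#' symmetricalUncertainty(x, x)  # 1
#' @export
symmetricalUncertainty <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ha <- shannonEntropy(a)
  hb <- shannonEntropy(b)
  if (ha + hb == 0) return(0)
  su <- 2 * informationFactor(a, b) / (ha + hb)
  min(max(su, 0), 1)                   # guard round-off at the boundaries
}

#' Feature-class relevance and feature-feature redundancy profile
#'
#' Computes \code{SU_FC[i]} = symmetrical uncertainty between feature i and
#' the class labels, and \code{SU_FF[i, j]} between every feature pair, after
#' discretizing the features (labels are already categorical). These are the
#' raw materials of the ant colony search heuristics.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @inheritParams discretize
#' @return a \linkS4class{RelevanceProfile}
#' @export
relevanceProfile <- function(table, nBins = 10L,
                             strategy = c("equal_width", "equal_frequency")) {
  stopifnot(is(table, "FeatureTable"))
  y <- sampleLabels(table)
  if (is.null(y)) stop("relevanceProfile requires a labeled table")
  strategy <- match.arg(strategy)
  codes <- discretizeTable(table, nBins, strategy)
  f <- ncol(codes)
  ycodes <- as.integer(y) - 1L
  suFC <- vapply(seq_len(f),
                 function(j) symmetricalUncertainty(codes[, j], ycodes),
                 numeric(1))
  suFF <- diag(0, f)
  for (i in seq_len(f)) {
    suFF[i, i] <- symmetricalUncertainty(codes[, i], codes[, i])
    if (i < f) {
      for (j in seq.int(i + 1L, f)) {
        s <- symmetricalUncertainty(codes[, i], codes[, j])
        suFF[i, j] <- s
        suFF[j, i] <- s
      }
    }
  }
  new("RelevanceProfile", suFC = suFC, suFF = suFF,
      featureIds = featureIds(table))
}

setMethod("show", "RelevanceProfile", function(object) {
  cat("RelevanceProfile over", length(object@suFC), "features\n")
  cat("SU_FC range:", sprintf("[%.4f, %.4f]", min(object@suFC),
                              max(object@suFC)), "\n")
  off <- object@suFF[upper.tri(object@suFF)]
  if (length(off))
    cat("SU_FF off-diagonal range:",
        sprintf("[%.4f, %.4f]", min(off), max(off)), "\n")
})

#' Heuristic desirability from feature-class relevance
#'
#' \eqn{\eta_i = 1 / (1 - SU_{FC,i})}: the higher a feature's dependence on
#' the class, the more desirable the node. The pole at \eqn{SU = 1} is
#' clamped: SU values are capped at \eqn{1 - \epsilon}, so
#' \eqn{\eta \le 1/\epsilon}.
#'
#' @param suFC numeric vector of SU values in \eqn{[0, 1]}
#' @param epsilon clamp constant, default 1e-6
#' @return numeric vector of desirabilities, all \eqn{\ge 1}, strictly
#'   increasing in `suFC`
#' @examples
#' heuristicFC(c(0, 0.5))  # 1, 2
#' @export
heuristicFC <- function(suFC, epsilon = 1e-6) {
  .check_unit_interval(suFC)
  1 / (1 - pmin(suFC, 1 - epsilon))
}

#' Heuristic desirability from feature-feature redundancy
#'
#' \eqn{\eta_{ij} = 1 / SU_{FF,ij}}: the more similar two features, the less
#' desirable it is to take both. The pole at \eqn{SU = 0} is clamped from
#' below at \eqn{\epsilon}, so \eqn{\eta \le 1/\epsilon}.
#'
#' @param suFF numeric matrix (or vector) of SU values in \eqn{[0, 1]}
#' @param epsilon clamp constant, default 1e-6
#' @return desirabilities of the same shape, strictly decreasing in `suFF`
#' @examples
#' heuristicFF(matrix(c(1, 0.25, 0.25, 1), 2))
#' @export
heuristicFF <- function(suFF, epsilon = 1e-6) {
  .check_unit_interval(suFF)
  1 / pmax(suFF, epsilon)
}

.check_unit_interval <- function(x, tol = 1e-9) {
  if (any(x < -tol) || any(x > 1 + tol))
    stop("SU values must lie in [0, 1]")
  invisible(TRUE)
}

#' Export a relevance profile as JSON
#'
#' Writes `su_fc` (array) and `su_ff` (matrix) plus feature ids.
#'
#' @param profile a \linkS4class{RelevanceProfile}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeRelevanceProfile <- function(profile, path) {
  stopifnot(is(profile, "RelevanceProfile"))
  jsonlite::write_json(
    list(feature_ids = profile@featureIds,
         su_fc = profile@suFC,
         su_ff = profile@suFF),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
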