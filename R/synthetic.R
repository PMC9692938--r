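## Synthetic generators with planted ground truth: labeled feature tables
## (informative / redundant / noise columns), class-patterned images, and
## corrupted-prediction confusion fixtures. Pure functions of their
## arguments (seed included).

#' Generate a labeled feature table with planted structure
#'
#' Classes are balanced. An informative feature for class c is drawn from
#' \eqn{N(\delta \sigma (c - (C-1)/2), \sigma)}, giving symmetric class-mean
#' separation of \eqn{\delta} noise-SD units between adjacent classes. Each
#' redundant feature is a chosen informative feature plus
#' \eqn{N(0, redundancyNoiseSd)} jitter. All remaining features are
#' label-independent \eqn{N(0, 1)} noise. Column positions are shuffled so
#' planted columns are not trivially ordered.
#'
#' @param nSamples total samples (split as evenly as possible over classes)
#' @param nFeatures total feature count F
#' @param nInformative number of class-dependent features
#' @param nRedundant number of noisy copies of informative features
#' @param nClasses number of classes C >= 2
#' @param effectSize class-mean separation \eqn{\delta} in noise-SD units
#' @param noiseSd within-class standard deviation \eqn{\sigma}
#' @param redundancyNoiseSd jitter SD of redundant copies
#' @param seed RNG seed
#' @return list with `table` (a labeled \linkS4class{FeatureTable}),
#'   `informative` and `redundant` (integer column indices), and
#'   `redundantSource` (the informative column each redundant copy tracks)
#' @examples
#' syn <- makeFeatureTable(seed = 42)
#' length(syn$informative)  # 8
#' @export
makeFeatureTable <- function(nSamples = 300L, nFeatures = 60L,
                             nInformative = 8L, nRedundant = 4L,
                             nClasses = 3L, effectSize = 1.5,
                             noiseSd = 1, redundancyNoiseSd = 0.5,
                             seed = 1L) {
  if (nInformative + nRedundant > nFeatures)
    stop("nInformative + nRedundant must not exceed nFeatures")
  if (nClasses < 2L) stop("need at least two classes")
  if (effectSize < 0) stop("effectSize must be non-negative")
  .with_seed(seed, {
    y <- factor(rep_len(paste0("c", seq_len(nClasses) - 1L), nSamples))
    y <- y[order(y)]
    n <- length(y)
    X <- matrix(stats::rnorm(n * nFeatures), n, nFeatures)
    classCenter <- effectSize * noiseSd *
      (as.integer(y) - 1 - (nClasses - 1) / 2)
    inf <- seq_len(nInformative)
    for (j in inf) X[, j] <- classCenter + stats::rnorm(n, 0, noiseSd)
    red <- if (nRedundant > 0L)
      nInformative + seq_len(nRedundant) else integer(0)
    src <- if (nRedundant > 0L)
      rep_len(inf, nRedundant) else integer(0)
    for (i in seq_along(red))
      X[, red[i]] <- X[, src[i]] + stats::rnorm(n, 0, redundancyNoiseSd)
    perm <- sample.int(nFeatures)
    X <- X[, perm, drop = FALSE]
    pos <- match(seq_len(nFeatures), perm)   # new position of old column j
    list(table = FeatureTable(X, y = y),
         informative = sort(pos[inf]),
         redundant = sort(pos[red]),
         redundantSource = pos[src])
  })
}

# one noise-free class pattern on a h x w grid, intensities in [0, 255];
# "blobs" varies the blob width by class, "gratings" uses orientation
# (class 2 falls back to a blob so three classes stay distinguishable)
.class_pattern <- function(class, h, w, pattern) {
  blob <- function(s) {
    rc <- (seq_len(h) - (h + 1) / 2) / h
    cc <- (seq_len(w) - (w + 1) / 2) / w
    255 * exp(-outer(rc^2, cc^2, `+`) / (2 * s^2))
  }
  if (pattern == "blobs") return(blob(0.08 + 0.06 * class))
  if (class == 2L) return(blob(0.15))
  if (class == 0L) {
    row <- 127.5 + 127.5 * sin(2 * pi * 4 * seq_len(h) / h)
    return(matrix(row, h, w))
  }
  col <- 127.5 + 127.5 * sin(2 * pi * 4 * seq_len(w) / w)
  matrix(col, h, w, byrow = TRUE)
}

#' Generate labeled synthetic images with class-dependent texture
#'
#' Class 0 is a horizontal grating, class 1 a vertical grating, class 2 a
#' centered Gaussian blob; independent Gaussian pixel noise is added and
#' intensities are clamped to `[0, 255]`.
#'
#' @param nPerClass images per class, >= 4
#' @param height,width image dimensions, >= 8
#' @param nClasses 2 or 3 classes
#' @param pattern `"gratings"` (blob used only for class 2) or `"blobs"`
#' @param noiseSd pixel noise SD on the 0-255 scale
#' @param seed RNG seed
#' @return list of [imageRecord()]s with labels `grating_h`, `grating_v`,
#'   `blob`
#' @export
makeImages <- function(nPerClass = 30L, height = 64L, width = 64L,
                       nClasses = 3L, pattern = c("gratings", "blobs"),
                       noiseSd = 20, seed = 1L) {
  pattern <- match.arg(pattern)
  if (height < 8L || width < 8L) stop("dimensions must be >= 8")
  if (nPerClass < 4L) stop("nPerClass must be >= 4")
  if (!nClasses %in% 2:3) stop("nClasses must be 2 or 3")
  labels <- c("grating_h", "grating_v", "blob")[seq_len(nClasses)]
  .with_seed(seed, {
    records <- list()
    for (cl in seq_len(nClasses) - 1L) {
      base <- .class_pattern(cl, height, width, pattern)
      for (i in seq_len(nPerClass)) {
        px <- base + matrix(stats::rnorm(height * width, 0, noiseSd),
                            height, width)
        px <- pmin(pmax(px, 0), 255)
        records[[length(records) + 1L]] <-
          imageRecord(px, label = labels[cl + 1L],
                      id = sprintf("%s_%03d", labels[cl + 1L], i))
      }
    }
    records
  })
}

#' Generate a corrupted-prediction fixture for metric tests
#'
#' True labels are balanced over C classes; each prediction is independently
#' corrupted with probability `errorRate` to a uniformly chosen *wrong*
#' class.
#'
#' @param C number of classes
#' @param n number of samples
#' @param errorRate corruption probability in `[0, 1]`
#' @param seed RNG seed
#' @return list with integer vectors `yTrue` and `yPred` (0-based codes)
#' @export
makeConfusionFixture <- function(C, n, errorRate, seed = 1L) {
  if (errorRate < 0 || errorRate > 1) stop("errorRate must lie in [0, 1]")
  .with_seed(seed, {
    yTrue <- rep_len(seq_len(C) - 1L, n)
    flip <- stats::runif(n) < errorRate
    yPred <- yTrue
    if (any(flip)) {
      wrong <- vapply(yTrue[flip], function(t) {
        others <- setdiff(seq_len(C) - 1L, t)
        others[sample.int(length(others), 1L)]
      }, integer(1))
      yPred[flip] <- wrong
    }
    list(yTrue = yTrue, yPred = yPred)
  })
}
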