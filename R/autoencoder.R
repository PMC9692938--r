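## Single-hidden-layer auto-encoder: z = h1(W1 x + b1), xhat = h2(W2 z + b2),
## trained by full-batch gradient descent on the mean squared reconstruction
## error. Analytic gradients are implemented here and verified against
## central finite differences in the test suite.

#' Auto-encoder configuration
#'
#' @param inputDim input dimensionality Dx (e.g. 4096 for 64 x 64 images)
#' @param hiddenDim hidden (code) dimensionality D1
#' @param transferEncoder,transferDecoder `"logistic"` (sigmoid) or
#'   `"linear"`
#' @param epochs number of full-batch gradient steps, >= 1
#' @param learningRate positive step size
#' @param seed seed for the weight initialization
#' @return a list of class `"AEConfig"`
#' @export
aeConfig <- function(inputDim, hiddenDim = 256L,
                     transferEncoder = c("logistic", "linear"),
                     transferDecoder = c("logistic", "linear"),
                     epochs = 200L, learningRate = 0.1, seed = 1L) {
  transferEncoder <- match.arg(transferEncoder)
  transferDecoder <- match.arg(transferDecoder)
  inputDim <- as.integer(inputDim); hiddenDim <- as.integer(hiddenDim)
  epochs <- as.integer(epochs)
  if (inputDim < 1L || hiddenDim < 1L) stop("dimensions must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(inputDim = inputDim, hiddenDim = hiddenDim,
                 transferEncoder = transferEncoder,
                 transferDecoder = transferDecoder,
                 epochs = epochs, learningRate = learningRate,
                 seed = as.integer(seed)),
            class = "AEConfig")
}

.transfer <- function(z, kind) {
  if (kind == "logistic") 1 / (1 + exp(-z)) else z
}

# derivative of the transfer expressed through its output a
.transfer_deriv <- function(a, kind) {
  if (kind == "logistic") a * (1 - a) else 1
}

# forward pass on an n x Dx matrix; returns activations
.ae_forward <- function(X, W1, b1, W2, b2, cfg) {
  A1 <- .transfer(sweep(X %*% t(W1), 2L, b1, `+`), cfg$transferEncoder)
  A2 <- .transfer(sweep(A1 %*% t(W2), 2L, b2, `+`), cfg$transferDecoder)
  list(A1 = A1, A2 = A2)
}

#' Encode samples to the hidden representation
#'
#' \eqn{z = h^{(1)}(W_1 x + b_1)} applied row-wise.
#'
#' @param X numeric vector (one sample) or matrix (samples in rows) of width
#'   `inputDim`
#' @param model an \linkS4class{AutoencoderModel}
#' @return matrix of hidden codes, one row per sample
#' @export
aeEncode <- function(X, model) {
  stopifnot(is(model, "AutoencoderModel"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(model@W1)) stop("input width must equal inputDim")
  cfg <- model@config
  .transfer(sweep(X %*% t(model@W1), 2L, model@b1, `+`), cfg$transferEncoder)
}

#' Decode hidden representations back to input space
#'
#' \eqn{\hat x = h^{(2)}(W_2 z + b_2)} applied row-wise.
#'
#' @param Z numeric vector or matrix of hidden codes of width `hiddenDim`
#' @param model an \linkS4class{AutoencoderModel}
#' @return matrix of reconstructions, one row per sample
#' @export
aeDecode <- function(Z, model) {
  stopifnot(is(model, "AutoencoderModel"))
  if (is.vector(Z)) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != ncol(model@W2)) stop("code width must equal hiddenDim")
  cfg <- model@config
  .transfer(sweep(Z %*% t(model@W2), 2L, model@b2, `+`), cfg$transferDecoder)
}

#' Mean squared reconstruction error
#'
#' Average of \eqn{(\hat x - x)^2} over all samples and input dimensions;
#' zero exactly when the reconstruction is perfect.
#'
#' @param X sample matrix (rows = samples)
#' @param model an \linkS4class{AutoencoderModel}
#' @return non-negative scalar
#' @export
reconstructionCost <- function(X, model) {
  stopifnot(is(model, "AutoencoderModel"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) stop("X must be non-empty")
  fw <- .ae_forward(X, model@W1, model@b1, model@W2, model@b2, model@config)
  mean((fw$A2 - X)^2)
}

# cost and analytic gradients for a parameter list on data X
.ae_cost_grad <- function(params, X, cfg) {
  n <- nrow(X); dx <- ncol(X)
  fw <- .ae_forward(X, params$W1, params$b1, params$W2, params$b2, cfg)
  diff <- fw$A2 - X
  cost <- sum(diff^2) / (n * dx)
  delta2 <- (2 / (n * dx)) * diff *
    .transfer_deriv(fw$A2, cfg$transferDecoder)
  delta1 <- (delta2 %*% params$W2) *
    .transfer_deriv(fw$A1, cfg$transferEncoder)
  list(cost = cost,
       grad = list(W1 = t(delta1) %*% X, b1 = colSums(delta1),
                   W2 = t(delta2) %*% fw$A1, b2 = colSums(delta2)))
}

#' Analytic gradient of the reconstruction cost
#'
#' Returns the cost and its gradient with respect to all parameters; exposed
#' so the backpropagation algebra can be checked against finite differences.
#'
#' @param params list with `W1`, `b1`, `W2`, `b2`
#' @param X sample matrix
#' @param config an [aeConfig()]
#' @return list with `cost` and `grad` (a list mirroring `params`)
#' @export
aeGradient <- function(params, X, config) {
  .ae_cost_grad(params, X, config)
}

.ae_init <- function(cfg) {
  r1 <- sqrt(6 / (cfg$inputDim + cfg$hiddenDim))
  .with_seed(cfg$seed, list(
    W1 = matrix(stats::runif(cfg$hiddenDim * cfg$inputDim, -r1, r1),
                cfg$hiddenDim, cfg$inputDim),
    b1 = numeric(cfg$hiddenDim),
    W2 = matrix(stats::runif(cfg$inputDim * cfg$hiddenDim, -r1, r1),
                cfg$inputDim, cfg$hiddenDim),
    b2 = numeric(cfg$inputDim)))
}

#' Train the auto-encoder by full-batch gradient descent
#'
#' Parameters start from a seeded uniform initialization and are updated by
#' full-batch gradient steps on the mean squared reconstruction error. If a
#' step would increase the cost, the step size is halved for that step
#' (simple backtracking), so the recorded cost sequence is non-increasing.
#' Training aborts with a diagnostic if the cost becomes non-finite.
#'
#' @param X sample matrix, rows = samples, width `inputDim`
#' @param config an [aeConfig()]
#' @return an \linkS4class{AutoencoderModel}
#' @examples
#' X <- matrix(runif(50 * 16), 50, 16)
#' m <- trainAutoencoder(X, aeConfig(16, 4, epochs = 50))
#' tail(m@costHistory, 1) <= m@costHistory[1]
#' @export
trainAutoencoder <- function(X, config) {
  stopifnot(inherits(config, "AEConfig"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != config$inputDim)
    stop("X width (", ncol(X), ") must equal inputDim (",
         config$inputDim, ")")
  params <- .ae_init(config)
  history <- numeric(config$epochs)
  cg <- .ae_cost_grad(params, X, config)
  for (e in seq_len(config$epochs)) {
    lr <- config$learningRate
    repeat {
      cand <- list(W1 = params$W1 - lr * cg$grad$W1,
                   b1 = params$b1 - lr * cg$grad$b1,
                   W2 = params$W2 - lr * cg$grad$W2,
                   b2 = params$b2 - lr * cg$grad$b2)
      candCg <- .ae_cost_grad(cand, X, config)
      if (!is.finite(candCg$cost))
        stop("training diverged: non-finite cost at epoch ", e)
      if (candCg$cost <= cg$cost || lr < 1e-12) break
      lr <- lr / 2
    }
    if (candCg$cost <= cg$cost) {
      params <- cand
      cg <- candCg
    }
    history[e] <- cg$cost
  }
  new("AutoencoderModel", W1 = params$W1, b1 = params$b1,
      W2 = params$W2, b2 = params$b2, config = unclass(config),
      costHistory = history)
}

#' Encode a sample matrix into a FeatureTable of hidden codes
#'
#' Row i of the result is the encoding of row i of `X`; feature ids are
#' `z0 ... z(D1-1)`; labels, when given, are carried through.
#'
#' @param X sample matrix
#' @param model a trained \linkS4class{AutoencoderModel}
#' @param y optional labels carried into the output table
#' @return a \linkS4class{FeatureTable} with `hiddenDim` columns
#' @export
extractFeatures <- function(X, model, y = NULL) {
  Z <- aeEncode(X, model)
  FeatureTable(Z, y = y,
               featureIds = paste0("z", seq_len(ncol(Z)) - 1L))
}

#' Save / load auto-encoder weights as JSON
#'
#' Weights are stored with shape metadata so a saved model round-trips
#' exactly (up to double-precision text representation).
#'
#' @param model an \linkS4class{AutoencoderModel}
#' @param path file path
#' @return `path` (save) or an \linkS4class{AutoencoderModel} (load)
#' @export
saveAutoencoder <- function(model, path) {
  stopifnot(is(model, "AutoencoderModel"))
  jsonlite::write_json(
    list(config = model@config,
         W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
         cost_history = model@costHistory),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname saveAutoencoder
#' @export
loadAutoencoder <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- j$config
  cfg$inputDim <- as.integer(cfg$inputDim)
  cfg$hiddenDim <- as.integer(cfg$hiddenDim)
  class(cfg) <- "AEConfig"
  new("AutoencoderModel",
      W1 = matrix(j$W1, cfg$hiddenDim, cfg$inputDim, byrow = FALSE),
      b1 = as.numeric(j$b1),
      W2 = matrix(j$W2, cfg$inputDim, cfg$hiddenDim, byrow = FALSE),
      b2 = as.numeric(j$b2),
      config = unclass(cfg), costHistory = as.numeric(j$cost_history))
}
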