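## Ant colony optimization over the feature graph: every feature is a node,
## ants build fixed-size subsets (tours), pheromone tau accumulates on
## features that appear in good subsets, and the static heuristic eta comes
## from symmetrical-uncertainty relevance/redundancy.

#' Configuration for the ant colony feature selector
#'
#' @param alpha pheromone exponent \eqn{\alpha \ge 0} in the transition rule.
#' @param beta heuristic exponent \eqn{\beta \ge 0}.
#' @param rho evaporation rate \eqn{\rho \in (0, 1)}: pheromone decays by the
#'   factor \eqn{(1 - \rho)} each iteration.
#' @param q0 exploitation threshold in \eqn{[0, 1]}: with probability `q0` an
#'   ant takes the greedy argmax step, otherwise it samples proportionally to
#'   desirability (the pseudo-random proportional rule).
#' @param nAnts number of ants per iteration.
#' @param nIterations number of iterations.
#' @param subsetSize tour length k (features per subset). `NULL` defers to
#'   \eqn{\lceil F/10 \rceil} at run time.
#' @param heuristicMode `"fc"` (feature-class relevance, a static per-node
#'   \eqn{\eta}), `"ff"` (feature-feature redundancy of a candidate relative
#'   to the last visited node) or `"combined"`
#'   (\eqn{\eta_j = \eta_{FC}(j) / (1 + SU_{FF}(last, j))}).
#' @param depositMode `"wrapper"` (deposit = 1 / cross-validated error of the
#'   evaluation classifier on the subset) or `"filter"` (deposit = mean
#'   static heuristic desirability of the subset).
#' @param classifier a [classifierSpec()] used by wrapper evaluation;
#'   defaults to 1-nearest-neighbor.
#' @param folds stratified cross-validation folds for wrapper mode.
#' @param nBins,binStrategy discretization used for the relevance profile
#'   (see [discretize()]).
#' @param epsilon clamp constant for the heuristic poles (see
#'   [heuristicFC()]).
#' @param acsConvention flip the greedy/probabilistic inequality: by default
#'   the greedy branch fires when \eqn{q < q_0}; with `acsConvention = TRUE`
#'   it fires when \eqn{q \ge q_0} (the two readings of the ambiguous
#'   published rule).
#' @param seed integer seed reproducing the whole run.
#' @return a validated list of class `"ACOConfig"`
#' @export
acoConfig <- function(alpha = 1, beta = 1, rho = 0.1, q0 = 0.8,
                      nAnts = 20L, nIterations = 50L, subsetSize = NULL,
                      heuristicMode = c("fc", "ff", "combined"),
                      depositMode = c("wrapper", "filter"),
                      classifier = NULL, folds = 5L,
                      nBins = 10L, binStrategy = "equal_width",
                      epsilon = 1e-6, acsConvention = FALSE, seed = 1L) {
  heuristicMode <- match.arg(heuristicMode)
  depositMode <- match.arg(depositMode)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (q0 < 0 || q0 > 1) stop("q0 must lie in [0, 1]")
  if (nAnts < 1L || nIterations < 1L) stop("nAnts and nIterations must be >= 1")
  if (!is.null(subsetSize) && subsetSize < 1L) stop("subsetSize must be >= 1")
  if (is.null(classifier)) classifier <- classifierSpec("knn", k = 1L)
  cfg <- list(alpha = alpha, beta = beta, rho = rho, q0 = q0,
              nAnts = as.integer(nAnts), nIterations = as.integer(nIterations),
              subsetSize = if (is.null(subsetSize)) NULL else
                as.integer(subsetSize),
              heuristicMode = heuristicMode, depositMode = depositMode,
              classifier = classifier, folds = as.integer(folds),
              nBins = as.integer(nBins), binStrategy = binStrategy,
              epsilon = epsilon, acsConvention = isTRUE(acsConvention),
              seed = as.integer(seed))
  class(cfg) <- "ACOConfig"
  cfg
}

#' Initialize the pheromone trail
#'
#' All features start with the same pheromone level of one.
#'
#' @param F number of features (nodes), >= 1
#' @return numeric vector of F ones
#' @export
initPheromone <- function(F) {
  F <- as.integer(F)
  if (F < 1L) stop("F must be >= 1")
  rep(1, F)
}

#' Node desirability tau^alpha * eta^beta
#'
#' The unnormalized attractiveness of each node in the transition rule.
#'
#' @param tau positive pheromone vector
#' @param eta positive heuristic vector of the same length
#' @param alpha,beta non-negative exponents
#' @return numeric vector of desirabilities
#' @export
nodeDesirability <- function(tau, eta, alpha = 1, beta = 1) {
  if (length(tau) != length(eta)) stop("tau and eta must have equal length")
  if (any(tau <= 0) || any(eta <= 0)) stop("tau and eta must be positive")
  abs(tau)^alpha * abs(eta)^beta
}

#' Transition probabilities over unvisited nodes
#'
#' Normalizes desirability over the unvisited nodes; visited nodes get zero
#' probability mass.
#'
#' @param desirability numeric vector from [nodeDesirability()]
#' @param visited integer vector of already visited node indices (1-based);
#'   may be empty
#' @return probability vector over all nodes, summing to 1
#' @export
transitionProbabilities <- function(desirability, visited = integer(0)) {
  F <- length(desirability)
  unvisited <- setdiff(seq_len(F), visited)
  if (length(unvisited) == 0L) stop("all nodes already visited")
  p <- numeric(F)
  total <- sum(desirability[unvisited])
  if (total <= 0) stop("zero total desirability over unvisited nodes")
  p[unvisited] <- desirability[unvisited] / total
  p
}

#' Choose the next node by the pseudo-random proportional rule
#'
#' Draws \eqn{q \sim U(0,1)}; on the greedy branch returns the argmax of
#' desirability over unvisited nodes (ties broken toward the lowest index),
#' otherwise samples from [transitionProbabilities()]. Consumes the current
#' RNG stream; seed upstream for reproducibility.
#'
#' @inheritParams transitionProbabilities
#' @param q0 exploitation threshold
#' @param acsConvention flip the branch inequality (see [acoConfig()])
#' @return the chosen node index (1-based), guaranteed unvisited
#' @export
chooseNext <- function(desirability, visited = integer(0), q0 = 0.8,
                       acsConvention = FALSE) {
  F <- length(desirability)
  unvisited <- setdiff(seq_len(F), visited)
  if (length(unvisited) == 0L) stop("all nodes already visited")
  q <- stats::runif(1)
  greedy <- if (acsConvention) q >= q0 else q < q0
  if (greedy) {
    d <- desirability[unvisited]
    unvisited[which.max(d)]          # which.max takes the first maximum
  } else {
    p <- transitionProbabilities(desirability, visited)
    sample.int(F, 1L, prob = p)
  }
}

# eta vector for the next step given the heuristic mode and the last node
.step_eta <- function(heur, mode, last) {
  switch(mode,
    fc = heur$etaFC,
    ff = if (is.na(last)) rep(1, length(heur$etaFC)) else heur$etaFF[last, ],
    combined = if (is.na(last)) heur$etaFC else
      heur$etaFC / (1 + heur$suFF[last, ]))
}

# internal tour construction on precomputed heuristics
.construct_tour <- function(tau, heur, k, config) {
  F <- length(tau)
  visited <- integer(0)
  visited[1L] <- sample.int(F, 1L)   # ant placed on a uniform random node
  while (length(visited) < k) {
    eta <- .step_eta(heur, config$heuristicMode, visited[length(visited)])
    d <- nodeDesirability(tau, eta, config$alpha, config$beta)
    visited <- c(visited, chooseNext(d, visited, config$q0,
                                     config$acsConvention))
  }
  visited
}

#' Construct one ant tour (a candidate feature subset)
#'
#' The ant starts on a uniform-random node and extends its tour by
#' [chooseNext()] until `subsetSize` distinct features are visited. Consumes
#' the current RNG stream.
#'
#' @param tau pheromone vector
#' @param profile a \linkS4class{RelevanceProfile}
#' @param config an [acoConfig()]
#' @return integer vector of distinct node indices in visit order
#' @export
constructTour <- function(tau, profile, config) {
  stopifnot(is(profile, "RelevanceProfile"))
  k <- .subset_size(config, length(tau))
  if (k > length(tau)) stop("subsetSize exceeds the number of features")
  heur <- .heuristics(profile, config)
  .construct_tour(tau, heur, k, config)
}

.heuristics <- function(profile, config) {
  list(etaFC = heuristicFC(profile@suFC, config$epsilon),
       etaFF = heuristicFF(profile@suFF, config$epsilon),
       suFF = profile@suFF)
}

.subset_size <- function(config, F) {
  if (is.null(config$subsetSize)) as.integer(ceiling(F / 10)) else
    config$subsetSize
}

# static per-node desirability used for filter-mode deposits
.filter_node_values <- function(heur, mode) {
  if (mode == "ff") rowMeans(heur$etaFF) else heur$etaFC
}

#' Score a feature subset
#'
#' Wrapper mode: stratified cross-validated misclassification error of the
#' evaluation classifier restricted to the subset; the score is
#' \code{1 / max(error, 1e-3)} (so a perfect subset scores 1000). Filter
#' mode: mean static heuristic desirability of the subset's nodes.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @param subset integer vector of feature indices (non-empty)
#' @param config an [acoConfig()]
#' @param heuristic optional precomputed per-node desirability vector for
#'   filter mode; computed from the table's relevance profile when missing
#' @param foldAssign optional precomputed fold assignment for wrapper mode
#' @return list with `value` (the score) and `cvError` (`NA` in filter mode)
#' @export
evaluateSubset <- function(table, subset, config, heuristic = NULL,
                           foldAssign = NULL) {
  stopifnot(is(table, "FeatureTable"))
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (is.null(sampleLabels(table))) stop("subset evaluation needs labels")
  if (config$depositMode == "wrapper") {
    err <- crossValError(table, subset, config$classifier,
                         folds = config$folds, seed = config$seed,
                         foldAssign = foldAssign)
    list(value = 1 / max(err, 1e-3), cvError = err)
  } else {
    if (is.null(heuristic)) {
      prof <- relevanceProfile(table, config$nBins, config$binStrategy)
      heuristic <- .filter_node_values(.heuristics(prof, config),
                                       config$heuristicMode)
    }
    list(value = mean(heuristic[subset]), cvError = NA_real_)
  }
}

#' Evaporate and deposit pheromone
#'
#' \eqn{\tau_i(t+1) = (1 - \rho)\,\tau_i(t) + \sum_{ants} \Delta\tau_i},
#' where each ant deposits its subset score on every feature of its tour.
#'
#' @param tau current pheromone vector
#' @param tours list of integer index vectors (one per ant)
#' @param scores numeric vector of subset scores aligned with `tours`
#' @param rho evaporation rate in (0, 1)
#' @return updated pheromone vector (strictly positive)
#' @export
updatePheromone <- function(tau, tours, scores, rho) {
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (length(tours) != length(scores))
    stop("tours and scores must be aligned")
  out <- (1 - rho) * tau
  for (i in seq_along(tours)) out[tours[[i]]] <- out[tours[[i]]] + scores[i]
  out
}

#' Run the ant colony feature selection
#'
#' Builds the relevance profile, initializes pheromone at one, then iterates:
#' each ant constructs a tour of `subsetSize` features, every tour is scored
#' ([evaluateSubset()]), pheromone evaporates and is reinforced
#' ([updatePheromone()]), and the global best subset is tracked. Fully
#' deterministic given `config$seed`.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @param config an [acoConfig()]
#' @return a \linkS4class{SelectionResult}
#' @examples
#' syn <- makeFeatureTable(nSamples = 90, nFeatures = 12, nInformative = 3,
#'                         nRedundant = 0, seed = 7)
#' res <- runACO(syn$table, acoConfig(depositMode = "filter",
#'                                    nIterations = 5, subsetSize = 3))
#' bestSubset(res)
#' @export
runACO <- function(table, config = acoConfig()) {
  stopifnot(is(table, "FeatureTable"))
  if (!inherits(config, "ACOConfig")) stop("config must come from acoConfig()")
  if (is.null(sampleLabels(table))) stop("runACO requires a labeled table")
  F <- nFeatures(table)
  k <- .subset_size(config, F)
  if (k > F) stop("subsetSize exceeds the number of features")

  profile <- relevanceProfile(table, config$nBins, config$binStrategy)
  heur <- .heuristics(profile, config)
  filterValues <- .filter_node_values(heur, config$heuristicMode)

  .with_seed(config$seed, {
    foldAssign <- if (config$depositMode == "wrapper")
      .stratified_folds(sampleLabels(table), config$folds) else NULL
    tau <- initPheromone(F)
    bestScore <- -Inf
    bestSubset <- integer(0)
    history <- numeric(config$nIterations)
    scoreCache <- new.env(parent = emptyenv())
    for (t in seq_len(config$nIterations)) {
      tours <- vector("list", config$nAnts)
      scores <- numeric(config$nAnts)
      for (a in seq_len(config$nAnts)) {
        tour <- .construct_tour(tau, heur, k, config)
        key <- paste(sort(tour), collapse = ",")
        if (is.null(scoreCache[[key]])) {
          sc <- if (config$depositMode == "filter")
            mean(filterValues[tour])
          else
            evaluateSubset(table, tour, config,
                           foldAssign = foldAssign)$value
          scoreCache[[key]] <- sc
        }
        tours[[a]] <- tour
        scores[a] <- scoreCache[[key]]
        if (scores[a] > bestScore) {
          bestScore <- scores[a]
          bestSubset <- sort(tour)
        }
      }
      tau <- updatePheromone(tau, tours, scores, config$rho)
      history[t] <- bestScore
    }
    cfgEcho <- config
    cfgEcho$classifier <- unclass(config$classifier)
    new("SelectionResult", bestSubset = as.integer(bestSubset),
        bestScore = bestScore, history = history, finalTau = tau,
        seed = config$seed, config = unclass(cfgEcho))
  })
}

#' @rdname SelectionResult-class
#' @export
setMethod("bestSubset", "SelectionResult", function(x) x@bestSubset)

#' @rdname SelectionResult-class
#' @export
setMethod("bestScore", "SelectionResult", function(x) x@bestScore)

#' @rdname SelectionResult-class
#' @export
setMethod("scoreHistory", "SelectionResult", function(x) x@history)

#' @rdname SelectionResult-class
#' @export
setMethod("finalPheromone", "SelectionResult", function(x) x@finalTau)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@bestSubset), "features, best score",
      format(object@bestScore, digits = 6), "over",
      length(object@history), "iterations (seed", object@seed, ")\n")
  cat("subset:", paste(object@bestSubset, collapse = ", "), "\n")
})

#' Uniform random feature subset (comparison baseline)
#'
#' @param F number of features
#' @param k subset size, k <= F
#' @param seed optional seed; when `NULL` the current RNG stream is used
#' @return integer vector of k distinct indices
#' @export
randomSubsetBaseline <- function(F, k, seed = NULL) {
  if (k > F) stop("k must not exceed F")
  if (is.null(seed)) sort(sample.int(F, k)) else
    .with_seed(seed, sort(sample.int(F, k)))
}

#' Serialize a SelectionResult to JSON
#'
#' Feature indices are written 0-based for language neutrality.
#'
#' @param result a \linkS4class{SelectionResult}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSelectionResult <- function(result, path) {
  stopifnot(is(result, "SelectionResult"))
  cfg <- result@config
  cfg$classifier <- cfg$classifier[c("family", "seed")]
  jsonlite::write_json(
    list(best_subset = result@bestSubset - 1L,
         best_score = result@bestScore,
         history = result@history,
         final_tau = result@finalTau,
         seed = result@seed,
         config = cfg),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
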