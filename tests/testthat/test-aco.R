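test_that("pheromone initialization and node desirability", {
  expect_equal(initPheromone(3), c(1, 1, 1))
  expect_equal(initPheromone(1), 1)
  expect_error(initPheromone(0), ">= 1")
  expect_equal(nodeDesirability(c(2, 1), c(1, 1), 1, 0), c(2, 1))
  expect_equal(nodeDesirability(c(2, 3), c(4, 1), 2, 0.5), c(8, 9))
  tau <- c(1, 2, 3)
  expect_equal(nodeDesirability(tau, rep(1, 3), 1, 0), tau)
  expect_error(nodeDesirability(1:2, 1:3), "equal length")
})

test_that("transition probabilities normalize over unvisited nodes", {
  p <- transitionProbabilities(rep(2, 4))
  expect_equal(p, rep(0.25, 4))
  expect_equal(transitionProbabilities(c(2, 1)), c(2 / 3, 1 / 3))
  expect_equal(transitionProbabilities(c(2, 1), visited = 1L), c(0, 1))
  expect_equal(sum(transitionProbabilities(runif(30) + 0.1, visited = 3:7)),
               1, tolerance = 1e-12)
  # strictly increasing in a node's own tau, others fixed
  d1 <- nodeDesirability(c(1, 1, 1), c(1, 1, 1))
  d2 <- nodeDesirability(c(2, 1, 1), c(1, 1, 1))
  expect_gt(transitionProbabilities(d2)[1], transitionProbabilities(d1)[1])
  expect_error(transitionProbabilities(c(1, 1), visited = 1:2), "visited")
  expect_error(transitionProbabilities(c(0, 0)), "zero total")
})

test_that("pseudo-random proportional rule: greedy branch and sampling", {
  set.seed(1)
  expect_equal(chooseNext(c(1, 5, 2), q0 = 1), 2L)
  expect_equal(chooseNext(c(3, 3), q0 = 1), 1L)   # tie -> lowest index
  # q0 = 0: pure proportional sampling; Monte-Carlo frequency check
  d <- c(1, 0.001, 0.001)
  set.seed(42)
  draws <- replicate(10000, chooseNext(d, q0 = 0))
  expect_equal(mean(draws == 1L), d[1] / sum(d), tolerance = 0.02)
  expect_error(chooseNext(c(1, 2), visited = 1:2), "visited")
})

test_that("pheromone update follows evaporation-plus-deposit exactly", {
  expect_equal(updatePheromone(c(1, 1), list(), numeric(0), rho = 0.1),
               c(0.9, 0.9))
  expect_equal(updatePheromone(c(1, 1), list(1L), 2, rho = 0.5), c(2.5, 0.5))
  # geometric decay with zero deposits
  tau <- rep(1, 5)
  for (t in 1:7) tau <- updatePheromone(tau, list(), numeric(0), 0.2)
  expect_equal(tau, rep(0.8^7, 5), tolerance = 1e-15)
  expect_error(updatePheromone(c(1, 1), list(), numeric(0), rho = 1), "rho")
  # bounded deposits keep tau within max(tau0, S/rho) + tau0
  set.seed(3)
  tau <- rep(1, 6)
  rho <- 0.3
  S <- 4  # max per-iteration total deposit on one feature
  for (t in 1:200) {
    tours <- list(sample.int(6, 3), sample.int(6, 3))
    tau <- updatePheromone(tau, tours, c(2, 2), rho)
    expect_true(all(tau > 0))
    expect_true(all(tau <= max(1, S / rho) + 1 + 1e-9))
  }
})

test_that("tours are distinct, seeded and of the requested length", {
  syn <- planted_table(seed = 2)
  prof <- relevanceProfile(syn$table)
  cfg <- acoConfig(depositMode = "filter", subsetSize = 8, seed = 10)
  set.seed(5)
  tour <- constructTour(initPheromone(60), prof, cfg)
  expect_length(tour, 8)
  expect_false(anyDuplicated(tour) > 0)
  set.seed(5)
  expect_identical(constructTour(initPheromone(60), prof, cfg), tour)
  # k = F gives a permutation
  small <- FeatureTable(matrix(rnorm(40), 10, 4), y = rep(0:1, 5))
  profS <- relevanceProfile(small, nBins = 3)
  cfgS <- acoConfig(depositMode = "filter", subsetSize = 4)
  set.seed(1)
  expect_setequal(constructTour(initPheromone(4), profS, cfgS), 1:4)
  cfgS$subsetSize <- 5L
  expect_error(constructTour(initPheromone(4), profS, cfgS), "exceeds")
})

test_that("subset scoring: wrapper inverts CV error, filter averages eta", {
  syn <- makeFeatureTable(nSamples = 150, nFeatures = 20, nInformative = 4,
                          nRedundant = 0, effectSize = 4, seed = 8)
  cfgW <- acoConfig(depositMode = "wrapper", seed = 2)
  sc <- evaluateSubset(syn$table, syn$informative, cfgW)
  expect_lt(sc$cvError, 0.05)
  expect_equal(sc$value, 1 / max(sc$cvError, 1e-3))
  # shuffled labels -> chance-level error
  shuf <- FeatureTable(featureMatrix(syn$table),
                       y = sample(sampleLabels(syn$table)))
  scS <- evaluateSubset(shuf, syn$informative, cfgW)
  expect_gt(scS$cvError, 1 - 1 / 3 - 0.15)
  # filter mode: mean of constant heuristic is that constant
  cfgF <- acoConfig(depositMode = "filter")
  scF <- evaluateSubset(syn$table, c(1L, 2L), cfgF,
                        heuristic = rep(2.5, 20))
  expect_equal(scF$value, 2.5)
  expect_error(evaluateSubset(syn$table, integer(0), cfgF), "non-empty")
})

test_that("runACO recovers planted informative features and is seeded", {
  syn <- planted_table(seed = 1)
  cfg <- acoConfig(depositMode = "filter", heuristicMode = "fc",
                   nAnts = 20, nIterations = 30, subsetSize = 8, seed = 3)
  res <- runACO(syn$table, cfg)
  expect_s4_class(res, "SelectionResult")
  expect_length(bestSubset(res), 8)
  expect_gte(sum(bestSubset(res) %in% syn$informative), 6)
  # history non-decreasing, best = max
  expect_true(all(diff(scoreHistory(res)) >= 0))
  expect_equal(bestScore(res), max(scoreHistory(res)))
  expect_true(all(finalPheromone(res) > 0))
  # determinism
  res2 <- runACO(syn$table, cfg)
  expect_identical(bestSubset(res2), bestSubset(res))
  expect_identical(scoreHistory(res2), scoreHistory(res))
  expect_identical(finalPheromone(res2), finalPheromone(res))
})

test_that("greedy single-ant run collapses to top-k by heuristic", {
  syn <- planted_table(seed = 4)
  prof <- relevanceProfile(syn$table)
  eta <- heuristicFC(prof@suFC)
  cfg <- acoConfig(depositMode = "filter", q0 = 1, nAnts = 1,
                   nIterations = 1, subsetSize = 5, seed = 9)
  res <- runACO(syn$table, cfg)
  # first node is random; the 4 greedy steps take the top eta nodes
  topk <- order(eta, decreasing = TRUE)[1:5]
  expect_gte(length(intersect(bestSubset(res), topk)), 4)
})

test_that("with beta = 0 and q0 = 1 the search ignores the heuristic", {
  # wrapper deposits do not involve eta, so with beta = 0 two runs that
  # differ only in the heuristic definition must be byte-identical
  syn <- makeFeatureTable(nSamples = 90, nFeatures = 12, nInformative = 3,
                          nRedundant = 0, seed = 6)
  mk <- function(mode) acoConfig(depositMode = "wrapper",
                                 heuristicMode = mode, beta = 0, q0 = 1,
                                 nAnts = 3, nIterations = 2,
                                 subsetSize = 3, folds = 3, seed = 12)
  r1 <- runACO(syn$table, mk("fc"))
  r2 <- runACO(syn$table, mk("ff"))
  expect_identical(bestSubset(r1), bestSubset(r2))
  expect_identical(scoreHistory(r1), scoreHistory(r2))
  expect_identical(finalPheromone(r1), finalPheromone(r2))
})

test_that("random baseline is uniform and reproducible", {
  expect_identical(randomSubsetBaseline(5, 5, seed = 1), 1:5)
  expect_identical(randomSubsetBaseline(30, 4, seed = 7),
                   randomSubsetBaseline(30, 4, seed = 7))
  expect_error(randomSubsetBaseline(3, 4), "exceed")
  set.seed(99)
  freq <- tabulate(replicate(1000, randomSubsetBaseline(10, 1)), 10)
  expect_true(all(abs(freq / 1000 - 0.1) < 0.04))
})

test_that("selection results serialize to JSON with 0-based indices", {
  syn <- makeFeatureTable(nSamples = 60, nFeatures = 10, nInformative = 2,
                          nRedundant = 0, seed = 3)
  res <- runACO(syn$table, acoConfig(depositMode = "filter",
                                     nIterations = 3, subsetSize = 2,
                                     seed = 5))
  f <- tempfile(fileext = ".json")
  writeSelectionResult(res, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(as.integer(j$best_subset), bestSubset(res) - 1L)
  expect_equal(j$best_score, bestScore(res))
  expect_length(j$history, 3)
})
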