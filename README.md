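# ACOSelect

Ant colony optimization (ACO) feature selection for image-based
computer-aided diagnosis pipelines, in R.

Medical-image classifiers usually work on large generic feature vectors —
auto-encoder codes or pre-trained CNN activations — in which most features
are noise or duplicates. ACOSelect finds a compact, relevant subset. Ants
walk a fully connected feature graph; each builds a size-`k` subset guided
by pheromone `tau` (what worked before) and a static heuristic `eta` derived
from symmetrical uncertainty:

- transition rule: from the unvisited nodes, take the argmax of
  `tau^alpha * eta^beta` with probability `q0`, otherwise sample
  proportionally to it;
- pheromone update: `tau(t+1) = (1 - rho) * tau(t) + sum of deposits`,
  each ant depositing its subset's score on the features it used;
- heuristics: `eta_FC = 1 / (1 - SU(feature, class))` rewards relevance,
  `eta_FF = 1 / SU(feature, feature)` penalizes redundancy, where
  `SU(X,Y) = 2 I(X,Y) / (H(X) + H(Y))` is normalized mutual information on
  discretized features;
- subset scores: inverse cross-validated classifier error (wrapper mode) or
  mean heuristic desirability (filter mode).

Around the selector the package provides the full pipeline: image
pre-processing (BT.601 grayscale, bilinear resize, row-major vectorization,
stratified 80-20 splits), a single-hidden-layer auto-encoder extractor
trained by full-batch gradient descent with verified analytic gradients, an
adapter contract for external CNN backbones (no weights bundled), a
six-family classifier harness (decision tree, SVM, KNN, random-forest
ensemble, naive Bayes, discriminant analysis), a macro-averaged
confusion-matrix metric suite (ACC, TPR, TNR, PPV, NPV, F1, MR, MCC), and
synthetic generators with planted ground truth so everything is testable
offline. See the vignette in `vignettes/aco-feature-selection.Rmd` for the
model details and design choices.

## Worked example

```r
library(ACOSelect)

syn <- makeFeatureTable(seed = 1)   # 300 samples x 60 features; 8 informative,
                                    # 4 redundant copies, 48 pure noise
res <- runACO(syn$table,
              acoConfig(depositMode = "filter", subsetSize = 8,
                        nIterations = 30, seed = 1))
res
#> SelectionResult: 8 features, best score 1.43192 over 30 iterations (seed 1 )
#> subset: 4, 10, 14, 29, 40, 48, 57, 58
sum(bestSubset(res) %in% syn$informative)
#> [1] 7

compareSelection(syn$table,
                 aco = acoConfig(depositMode = "filter", subsetSize = 8,
                                 nIterations = 30), seed = 1)
#>        strategy  k   acc    f1   mcc
#> 1  all_features 60 0.783 0.787 0.680
#> 2    aco_subset  8 0.967 0.967 0.950
#> 3 random_subset  8 0.550 0.561 0.342
```

The selector recovered 7 of the 8 planted informative features, and its
8-feature subset classifies held-out samples at 96.7% accuracy — better
than all 60 features (78.3%, the noise hurts 1-NN) and far better than a
random subset of the same size (55.0%).

For images, `runPipeline()` chains split -> pre-process -> auto-encoder ->
ACO -> classify:

```r
recs <- makeImages(nPerClass = 30, seed = 5)   # 3 classes of 64x64 textures
out <- runPipeline(recs, pipelineConfig(
  aco = acoConfig(depositMode = "filter", subsetSize = 20,
                  nIterations = 30), seed = 7))
out$report@overall[["acc"]]
#> [1] 1
```

A thin command-line wrapper with `synth`, `select` and `pipeline`
subcommands lives in `inst/scripts/acoselect.R`.

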