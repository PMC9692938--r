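---
title: "Ant colony feature selection with symmetrical-uncertainty heuristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant colony feature selection with symmetrical-uncertainty heuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ACOSelect)
```

## The problem

Computer-aided diagnosis pipelines for medical images (chest X-rays, brain
MRI slices) typically extract hundreds to thousands of features per image —
auto-encoder codes or activations of a pre-trained convolutional network —
and most of those features are uninformative or redundant. ACOSelect
implements the middle stage of such a pipeline: given a labeled feature
table, find a compact subset of features that preserves (or improves)
classification accuracy. The search is an ant colony optimization (ACO)
over the feature graph, guided by entropy-based relevance scores, flanked by
an auto-encoder feature extractor on one side and a pluggable classifier
harness on the other.

## Relevance and redundancy from information theory

All relevance scores are computed on discretized features. For a discrete
sample $X$ with empirical (maximum-likelihood) probabilities $p(x_i)$,

$$H(X) = -\sum_i p(x_i)\,\log_2 p(x_i),$$

with $0 \log 0 = 0$; `jointEntropy()` and `conditionalEntropy()` are the
bivariate analogues, and the mutual information (the *information factor*)
is $I(X,Y) = H(X) - H(X \mid Y)$. Because $H$ grows with the number of
categories, the selector uses the normalized *symmetrical uncertainty*

$$SU(X,Y) = \frac{2\,I(X,Y)}{H(X) + H(Y)} \in [0,1],$$

which is 1 for identical non-constant variables and 0 for empirically
independent ones. When both variables are constant, $SU$ is $0/0$; we define
it as 0 (constants carry no information). All logarithms are base 2; $SU$ is
invariant to the base, so this choice only affects reported entropies.

Two score families feed the search, computed by `relevanceProfile()`:
$SU_{FC}$ (each feature against the class labels — relevance) and $SU_{FF}$
(each feature pair — redundancy). They become heuristic desirabilities

$$\eta^{FC}_i = \frac{1}{1 - SU_{FC,i}}, \qquad
  \eta^{FF}_{ij} = \frac{1}{SU_{FF,ij}},$$

so relevance attracts and redundancy repels. Both forms have poles (at
$SU_{FC} = 1$ and $SU_{FF} = 0$); we clamp the argument with
$\epsilon = 10^{-6}$ (configurable), capping $\eta$ at $10^6$. This keeps
desirabilities finite without changing any ordering.

**Discretization.** Entropy on continuous features requires binning. The
default is equal-width binning with $B = 10$ bins per feature — a
deterministic, standard choice for SU-based selection; equal-frequency
binning is available (`strategy = "equal_frequency"`). A constant feature
collapses to a single bin rather than erroring. $B$ trades bias for
variance: fewer bins blur class structure, many bins inflate $SU$ between
unrelated continuous features at small $n$. At the package's default table
sizes (hundreds of samples), $B = 10$ keeps the independent-pair $SU$ well
below the planted-signal $SU$.

## The ant colony search

Features are nodes of a fully connected graph. Each of $m$ ants builds a
tour of exactly $k$ distinct features; pheromone $\tau$ (initialized at 1 on
every node) accumulates on features that appear in good subsets.

At each step an ant at node $i$ draws $q \sim U(0,1)$ and either exploits —
takes the unvisited node maximizing $\tau_u^\alpha \eta_u^\beta$ (when
$q < q_0$; ties go to the lowest index) — or explores, sampling the next
node with probability

$$P_u = \frac{\tau_u^\alpha\,\eta_u^\beta}
             {\sum_{v \notin \text{visited}} \tau_v^\alpha\,\eta_v^\beta}.$$

The published form of this rule leaves the two inequality directions
ambiguous; we implement greedy-when-$q < q_0$ (which matches the canonical
ant colony system's exploit branch) and expose `acsConvention = TRUE` to
flip the reading.

After all ants finish an iteration, pheromone evaporates and is reinforced:

$$\tau_i(t+1) = (1-\rho)\,\tau_i(t) + \sum_{\text{ants } a} \Delta\tau_i^a,
\qquad \Delta\tau_i^a = \begin{cases} s_a & i \in \text{tour}_a\\ 0 &
\text{otherwise,}\end{cases}$$

where every ant deposits (not just the best one), matching the printed sum
over ants. With deposits bounded by $S$ per feature per iteration, $\tau$
stays within $\max(\tau_0, S/\rho) + \tau_0$ and strictly positive — both
verified as properties in the test suite.

**Subset scores $s_a$.** Two modes:

* `wrapper`: $s_a = 1/\max(\text{err}_a, 10^{-3})$ where $\text{err}_a$ is
  the stratified 5-fold cross-validated misclassification rate of the
  evaluation classifier (default 1-nearest-neighbor: fast and
  parameterless) restricted to the subset. The floor caps a perfect
  subset's score at 1000. Fold assignment is drawn once per run, so a
  subset always receives the same score within a run.
* `filter`: the source material describes the filter deposit only as an
  average over the selected nodes, which is dimensionally odd for
  fixed-length tours; we interpret it as the mean *static heuristic
  desirability* of the subset's nodes — $\eta^{FC}$ in `fc` and `combined`
  modes, the row-mean of $\eta^{FF}$ in `ff` mode. This makes filter
  deposits label-driven, cheap, and independent of $\tau$ (no
  self-reinforcement artifacts).

**Heuristic modes.** `fc` uses the static $\eta^{FC}$ per node. `ff` scores
a candidate $j$ by $\eta^{FF}_{\text{last},\,j}$ relative to the ant's last
visited node. The source names both criteria but no combination rule;
`combined` uses $\eta_j = \eta^{FC}_j / (1 + SU_{FF}(\text{last}, j))$,
which rewards relevance and damps redundancy on the same $[1, \infty)$
scale without a second exponent to tune.

**Defaults.** No numeric values are published for the ACO
hyper-parameters; the defaults $\alpha = 1$, $\beta = 1$, $\rho = 0.1$,
$q_0 = 0.8$, 20 ants, 50 iterations are conventional for ant-colony-system
variants, and the tour length defaults to $\lceil F/10 \rceil$ so deposits
are comparable across ants and runs. All are configurable in
`acoConfig()`.

**Determinism.** A single seeded RNG stream drives ant placement, the
$q$-draws, proportional sampling and fold assignment; `runACO()` with the
same seed is bit-reproducible, and the global-best score history is
non-decreasing by construction.

## The auto-encoder extractor

A single-hidden-layer auto-encoder maps $x \in \mathbb{R}^{D_x}$ to
$z = h^{(1)}(W_1 x + b_1) \in \mathbb{R}^{D_1}$ and back via
$\hat{x} = h^{(2)}(W_2 z + b_2)$. The cost is the mean squared
reconstruction error over samples and dimensions — the standard choice when
only "error between input and reconstruction" is specified. Transfer
functions default to the logistic sigmoid (inputs are normalized to $[0,1]$
first, matching the sigmoid output range); linear transfers are available
and make the model analytically transparent: with $D_1 \ge
\operatorname{rank}(X)$ and linear maps the achievable cost approaches 0 on
noiseless low-rank data, which the tests verify, and with matched capacity
training recovers the principal subspace.

Training is full-batch gradient descent from a seeded Glorot-uniform
initialization with a fixed learning rate — the simplest faithful
optimizer. One numerical safeguard is added: if a step would increase the
cost, the step size is halved for that step, so the recorded cost sequence
is non-increasing and training cannot silently diverge (a non-finite cost
aborts with a diagnostic). Backpropagation gradients are exposed via
`aeGradient()` and checked against central finite differences to $10^{-5}$
relative error in the suite. The default hidden size for 4096-pixel inputs
is 256 ($16\times$ compression); the bundled pipeline experiments use 64,
which is ample for the synthetic image classes.

## Image pre-processing and splits

`prepImages()` converts to grayscale with BT.601 luma ($0.299R + 0.587G +
0.114B$, rounded to keep 8-bit semantics), resizes with center-aligned
bilinear interpolation (delegated to EBImage and verified against a
closed-form oracle), flattens row-major (a $64\times 64$ image becomes a
4096-vector) and rescales to $[0,1]$. Aspect ratio is not preserved —
images are stretched to the target square, the simplest reading of a fixed
target resolution.

`stratifiedSplit()` partitions each class separately after a seeded
shuffle. Published per-class 80-20 counts are not consistent with a single
rounding rule across datasets, so the rule is explicit:
`floor_train` or `nearest_train` (round half up). On the 708/1426/930
three-class profile, `nearest_train` yields 566/1141/744 training slices —
reproduced exactly in the tests — while four-figure chest X-ray class sizes
match `floor_train`.

External CNN extractors are supported only through an adapter contract
(`registerBackbone()` / `cnnFeatureAdapter()`): the conventional names
carry fixed output widths (alexnet 4096, googlenet 1000, resnet50 2048,
densenet201 1920) and a registered function must honor its declared width.
No pre-trained weights are bundled.

## Metrics

`macroMetrics()` reduces a $C$-class confusion matrix one-vs-rest per class
and computes ACC, TPR, TNR, PPV, NPV, F1, misclassification rate and the
Matthews correlation coefficient

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Multiclass aggregation is macro-averaging of the per-class one-vs-rest
values (no aggregation rule is published for the single values reported on
3-class problems; macro-OVR is standard and reproducible, and per-class
values are retained in the report). Overall accuracy always comes from the
matrix trace with $MR = 1 - ACC$, so the pair is consistent by
construction. Zero-denominator rates (e.g. PPV with no positive
predictions) are reported as 0 and flagged in the report rather than
returned as NaN.

## Synthetic data: what it emulates and what it does not

`makeFeatureTable()` plants a known signal: informative features get
class-dependent means at $\delta\sigma\,(c - (C-1)/2)$ (one knob, symmetric
separation), redundant features are informative columns plus
$N(0, 0.5)$ jitter — close enough to rank in the top 5% of all pairwise
$SU_{FF}$ values while staying below their source in $SU_{FC}$ — and the
rest is independent $N(0,1)$ noise; column order is shuffled. The default
spec (300 samples, 60 features, 8 informative, 4 redundant, 3 classes,
$\delta = 1.5$, $\sigma = 1$) is small enough for minute-scale tests yet
hard enough that random subsets clearly underperform selected ones.
`makeImages()` builds grating/blob classes with additive pixel noise
(SD 20 on the 0-255 scale) so orientation and shape — not brightness —
separate the classes.

These generators validate the machinery, not clinical performance: Gaussian
class-conditional features have none of the heavy tails, batch effects or
label noise of real radiology data, and the image classes are far cleaner
than pathology. Passing tests demonstrate correctness of the algorithms and
recovery under controlled signal, not expected accuracy on hospital data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery experiment at
300 samples x 60 features (20 ants, 30 iterations, $k = 8$, five seeds) and
the end-to-end pipeline at 90 images of $64 \times 64$ (hidden size 64, 150
epochs, select 20 of 64 codes) — sizes chosen so the full suite completes
in a couple of minutes on one core while leaving clear headroom between
planted signal and noise. Degenerate inputs are handled explicitly:
constant features discretize to one bin and have $SU = 0$ by definition;
argmax ties break to the lowest index; empty tables, length mismatches,
out-of-range $SU$ values, exhausted (all-visited) graphs and classes
smaller than the fold count raise immediate errors rather than propagating
nonsense.

## Known limitations

* Filter-mode deposits are our interpretation of an ambiguous published
  rule (see above); wrapper mode is unambiguous but costlier.
* Equal-width binning is a bias/variance compromise; no continuous
  (kernel) entropy estimators are provided by design.
* The auto-encoder is deliberately one hidden layer with full-batch
  descent: no stacking, denoising, sparsity or mini-batching.
* Classifier internals are delegated to rpart/e1071/class/randomForest/
  MASS; only their seeds and echoed hyper-parameters are managed here.

## A worked run

```{r example, eval = FALSE}
syn <- makeFeatureTable(seed = 1)       # 300 x 60, 8 informative planted
res <- runACO(syn$table,
              acoConfig(depositMode = "filter", subsetSize = 8,
                        nIterations = 30, seed = 1))
sum(bestSubset(res) %in% syn$informative)   # 7 of 8 on this seed
compareSelection(syn$table,
                 aco = acoConfig(depositMode = "filter", subsetSize = 8,
                                 nIterations = 30), seed = 1)
```
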