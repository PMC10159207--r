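---
title: "Methods: exact tree-ensemble Shapley attribution for metabolomics classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact tree-ensemble Shapley attribution for metabolomics classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboshap)
```

This vignette is the package's own account of its methods: the models and
value functions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, the
numerical conventions, and the design choices that were genuinely open.

## The attribution model

A trained classifier is treated as a cooperative game: the feature values
of one sample are the players, the model output is the payout, and the
Shapley value is the unique attribution satisfying symmetry, dummy and
additivity. For feature $i$ out of $N$,

$$\phi_i \;=\; \sum_{S \subseteq F \setminus \{i\}}
\frac{|S|!\,(N-|S|-1)!}{N!}\,
\bigl[\mathrm{val}(S \cup \{i\}) - \mathrm{val}(S)\bigr],$$

and the attributions reconstruct the prediction exactly (local accuracy):
$\mathrm{val}(\varnothing) + \sum_i \phi_i = f(x)$.

Everything therefore hinges on the **value function** $\mathrm{val}(S)$ —
what "the model output when only $S$ is known" means. For tree ensembles
the package uses the *path-dependent conditional expectation*: descending
a tree, a node that splits on a feature in $S$ is routed the way $x$ goes,
while a node splitting on any other feature returns the cover-weighted
average of its two subtrees, where *cover* is the number of training
samples that passed through each child. This value function needs no
background dataset — the training distribution is already summarized in
the covers — which is why every node of an ingested model must carry a
cover and why `validate_tree()` enforces
$\mathrm{cover}(j) = \mathrm{cover}(\mathrm{left}) + \mathrm{cover}(\mathrm{right})$
exactly. An *interventional* value function (averaging composite samples
over an explicit background matrix) is available as an option in
`tree_conditional_value()`; it is equally exact but answers a different
question, and generally yields different attributions. Local accuracy is
always asserted against the engine's own value function, i.e. against
$\mathrm{val}(\varnothing)$, the cover-weighted mean leaf value. Because
plotting conventions elsewhere sometimes anchor waterfalls at the *average
prediction over the explained set* instead, `explain_matrix()` reports
that quantity too (`mean_output`), side by side with the cover-derived
`base_value`; the two are close but not identical, and only the latter
participates in the conservation identity.

### Two routes to the same numbers

`shapley_bruteforce()` evaluates the definition directly over all $2^N$
coalitions. It is exponential and guarded at $N \le 20$, but it is
*independent* of any clever algorithm, which makes it the oracle.
`tree_shap()` computes identical values in $O(T L D^2)$ per sample by
propagating, down each root-to-leaf path, the weighted proportions of
coalitions of every size (the extend step), undoing the extension when a
path feature repeats or when a leaf's contribution is collected (unwind).
Features repeated along one path are merged first, so the bookkeeping is
over unique path features. The test suite drives both routes over
randomly structured ensembles and requires agreement to $10^{-8}$ (they
agree to $\sim 10^{-15}$ in practice); the traversal also exposes a
node-visit counter, checked against the budget $T(2L-1)(D+2)^2$ on a
500-feature, 50-tree, depth-6 problem.

### Output scale for boosted models

For forests whose trees vote probabilities, the summed output *is* the
class probability and attributions live on that scale. Ingested boosting
models (`output_kind = "margin"`) are explained on the **margin (log-odds)
scale**: Shapley values are computed for the raw summed output and the
logistic link is applied only when a response-scale prediction is
requested. Attributing the *linked* output would break the per-tree
additivity that the polynomial algorithm relies on; margin-scale
explanation is the standard convention for boosted ensembles and keeps
local accuracy exact.

## The classification pipeline

The pipeline mirrors a conventional metabolomics ML workflow:

1. **Split** — test fraction defaults to 1/6 with nearest-integer
   rounding, so 184 samples yield a 31-sample test set. Stratification is
   on by default (small test sets otherwise drift in class balance), with
   a recorded seed; per-class test counts are apportioned by largest
   remainder, which keeps proportions within one sample per class.
2. **Volcano selection, train-only** — a feature is kept iff
   $|\log_2 \mathrm{FC}| > 0.5$ *and* $p < 0.05$, both strict. The fold
   change is computed on raw group means (with a pseudo-count of half the
   feature's smallest positive value when a group mean is zero); the
   $p$-value is a two-sided pooled-variance Student's $t$ on
   $\log_2$ abundances. The scale choice matters: tests on logged values
   and fold changes on raw means is the standard volcano construction,
   and the logged test is far better behaved for log-normal intensities.
   No multiple-testing correction is applied by default, matching the
   raw-$p$ convention of volcano selection; a Benjamini–Hochberg option
   exists (`adjust = "BH"`) for users who want it. Features with zero
   variance in both groups get $p = 1$.
3. **Log + autoscale, fitted on train** — element-wise $\log_{10}$ then
   per-feature centering and unit-variance scaling ($n-1$ denominator)
   using training statistics only; the test table never contributes to
   the scaler. The log base is irrelevant downstream: a base change is a
   per-feature linear rescale absorbed exactly by autoscaling (asserted
   to $10^{-10}$). Zero-variance training features are dropped from both
   partitions with a warning.
4. **Tuning** — exhaustive grid search (a single-parameter grid is a
   linear search) under stratified $k$-fold cross-validation, scored by
   mean rank-based ROC AUC with midrank ties. Score ties are broken
   toward the simpler model — fewer PLS components, or fewer
   trees × depth — then by grid order, so the search is deterministic.
   Default folds: 10; default grids are small and overridable
   (`n_components` 1–5; 100 trees at depth {3, 6, 10}).
5. **Evaluation and explanation** — held-out AUC, percent-of-total
   confusion rates, a Tree SHAP matrix of the test set for forests (plus
   Gini importance), VIP for PLS-DA, and the analytics artifacts.

The tuning stage receives only the training partition by construction;
test labels are first touched at the evaluation step.

### PLS-DA conventions

NIPALS PLS1 with X-deflation; the 0/1 response is centered internally.
For a single response each weight vector is the deflated $X^\top y$
direction, so the inner loop converges in one pass; the iteration cap
(500) and tolerance ($10^{-12}$) are retained as guards. If the residual
covariance vanishes before the requested number of components (for
example, a response orthogonal to every column), extraction stops and the
model truncates to the achievable components — the degenerate case yields
zero coefficients rather than an error. Requesting more components than
$\mathrm{rank}(X)$ is an error that reports the achievable rank. The
classification boundary assigns $\hat{Y} = 0.5$ to the positive class: the
standard rule defines only the strict inequalities, and a deterministic
convention is required. VIP uses Wold's formula with per-component
explained response sum of squares as weights; $\sum_j \mathrm{VIP}_j^2 = p$
is an algebraic identity and is asserted to $10^{-8}$.

### The reference forest

The built-in trainer exists so that cover-annotated ensembles can be grown
reproducibly without external dependencies: bagged greedy CART with Gini
impurity, a seeded random feature subset of size `max_features`
(default $\lceil\sqrt{p}\rceil$) per node, midpoint thresholds, and ties
broken by lowest feature index then lowest threshold — every convention
fixed so training is bit-stable under a seed. Leaves carry the
positive-class fraction of in-bag samples, and covers record the in-bag
routing, which is exactly what the path-dependent value function needs.
The forest output is the *average of leaf probabilities*, not a majority
vote: attribution requires a continuous output, and averaged probabilities
are what the explanation plots decompose. Externally trained models enter
through `ingest_ensemble()` (JSON node arrays including covers) or
`ingest_randomForest()` (covers reconstructed by routing a supplied
matrix, typically the training data); prediction equivalence against the
source model is part of the test suite.

## The synthetic generator

`synth_generate()` emulates the structure of the targeted studies:
80–200 samples, tens to hundreds of features, log-normal abundances
(exponentials of correlated Gaussians), a few strongly discriminative
metabolites, and balanced-ish binary classes. Effects are multiplicative:
an informative feature's natural-log mean is shifted by
$\mathrm{effect} \times \ln 2$ in the positive class, so the expected
log2 fold change of group geometric means equals the configured effect —
and, because both classes share the same log-scale variance, the raw-mean
fold change seen by the volcano agrees in expectation.

Defaults: $\mu = 3$ and $\sigma = 0.5$ on the natural-log scale. The
$\sigma$ choice corresponds to a between-sample coefficient of variation
of roughly 50%, typical of biological variation in urine or serum
metabolite intensities; it is the single knob that controls how hard the
planted-recovery problem is, and it is deliberately fixed once here rather
than per test.

The `urine_sex_preset()` mirrors a urine sex-classification study at desk
scale: 184 samples (101 "male"/83 "female"), 184 features, a +2.0 log2
marker (testosterone-glucuronide-like), a −1.5 marker
(*p*-anisic-acid-like), and a correlated pair ($\rho = 0.8$) in which one
member carries a +1.0 effect and the other is an uninformative hitchhiker
— the configuration used for dependence/interaction demonstrations and
for the recovery study (100 seeded replicates; the strong marker is
expected to rank first by both mean-|SHAP| and VIP in at least 95, with
held-out AUC above 0.9 in at least 90).

What the generator does **not** emulate: batch effects, missingness
mechanisms, instrument drift, heavy-tailed or zero-inflated intensity
distributions, and realistic genome-wide correlation structure beyond the
configured blocks. Passing recovery tests on this generator therefore
demonstrates that the pipeline's statistics behave as designed under a
clean log-normal model — not that any particular real dataset will yield
the same rankings.

## Numerical conventions, in one place

* Routing: left iff $x_f \le \mathrm{threshold}$; the classification
  boundary $\hat{Y} = 0.5$ (and forest probability 0.5) is positive.
* Local accuracy enforced at $10^{-8}$ when an `attribution` is built;
  oracle equivalence asserted at $10^{-8}$; symmetry at $10^{-12}$;
  per-tree additivity at $10^{-10}$.
* Cover additivity at internal nodes: tolerance $10^{-9}$ (relative for
  large covers). Brute-force guard: $N \le 20$, overridable.
* Pseudo-counts: half the feature's smallest positive value, applied
  before fold changes, logs, and scaling; non-positive values with
  pseudo-counting disabled are an error.
* Beeswarm colour: per-feature min-max scaling to $[0,1]$; constant
  features map to 0.5.
* Embedding: top-2 right singular directions of the centered SHAP matrix;
  each component's sign fixed by making its largest-magnitude loading
  positive; a single-feature matrix gets a zero second coordinate.
* Supervised clustering: Euclidean distance, average linkage (recorded in
  the output metadata). Dependence auto-interaction: the other feature
  whose values maximize $|r|$ against the target's SHAP column.
* Decomposition ordering: $|\phi|$ descending, ties by feature index.
* Confusion rates: percentages of the *total* test size, so the four
  rates partition 100%.
* All randomness flows through explicit integer seeds; repeated runs are
  bit-identical.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to exercise every code path
while keeping the suite quick: oracle equivalence on 50 random ensembles
($T \le 10$, depth $\le 4$, $N \le 10$) with 4 samples each; the
node-visit budget at $N = 500$, $T = 50$, $D = 6$; null calibration at
500 features; and the recovery study at the preset's full 184 × 184 with
100-tree forests over 100 seeds.

## Known limitations

* The polynomial engine is pure R; it is comfortably fast at the package's
  target scale (hundreds of features, tens of thousands of node visits per
  sample) but is not tuned for very deep trees or million-sample
  explanation sets.
* Pairwise SHAP interaction values, kernel SHAP for non-tree models, and
  multi-class tasks are out of scope.
* Boosting models are ingested, never trained here; their explanations are
  on the margin scale by design.
* The pipeline's cross-validation tunes on the already-transformed
  training matrix; the split-level selection and scaling are leakage-free,
  but per-fold re-selection is not performed.
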