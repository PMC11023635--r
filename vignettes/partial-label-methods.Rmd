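---
title: "Partial-label learning for single-cell classification: models, training loops and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-label learning for single-cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plcell)
```

## The problem

Annotating single-cell transcriptomic profiles with cell types (or positions
along a differentiation lineage) usually presumes a fully supervised training
atlas. In practice much of the annotation available is *partial*: for many
cells, marker genes or a coarse reference only narrow the identity down to a
small set of candidate labels, exactly one of which is correct. `plcell`
treats this as a partial-label learning problem. A training set

* `Ds` holds `l` fully supervised pairs `(x_i, y_i)`,
* `Dpl` holds `m` partially labeled pairs `(x_i, Y_i)` with `|Y_i| = k` and
  the true label hidden inside `Y_i`,

and the label set `Y` may carry a rooted tree (a lineage hierarchy) whose
shortest-path edge counts form the dissimilarity matrix `C`.

## The objective and the two training loops

All classifiers expose a score `score(x, c)` for every label and predict by
argmax (ties to the smallest label index, everywhere, so every computation is
deterministic). Supervised training minimises

```
Omega(W) + (mu / l) * sum_i loss(f_W, x_i, y_i)
```

and partial-label training adds the best-case loss over each candidate set:

```
Omega(W) + (mu/l) * sum_Ds loss(f_W, x_i, y_i)
         + (lambda/m) * sum_Dpl min_{y in Y_i} loss(f_W, x_i, y)
```

The minimum inside the second sum couples labeling and parameters, so the
package trains by alternation:

* **IRL (iterative refinement learning)** — infer the most likely candidate
  label for every partial sample under the current model, then take *one*
  refinement epoch of minibatch gradient descent on the resulting fully
  labeled view. Applicable to every gradient-trainable family.
* **IFR (iterative full retraining)** — the same alternation, but with a
  fresh model trained to convergence at each iteration. This is the only
  option for tree ensembles, and it is sensitive to expressivity: a model
  that can interpolate any labeling reproduces its initial random labeling
  and never moves. `ifr_fit()` detects that degenerate fixed point (first
  iteration, labeling unchanged, training predictions exactly reproduce it)
  and warns.

At test time, prediction is either unrestricted over `Y` or restricted to a
candidate set when one is available; the two metrics (`precision`,
`precision_with_prior`) mirror that choice. Restricting the argmax to a set
that contains the truth can never turn a correct prediction wrong under the
fixed tie-break, so prior-restricted precision dominates plain precision —
asserted on every benchmark run.

### Stopping, initialisation and other decisions left open by the alternation

* "Optimization complete" is made concrete as: the inferred labeling
  unchanged for 5 consecutive IRL iterations (a single fixed point for IFR),
  or caps of 300 (IRL) / 10 (IFR) iterations.
* One IRL refinement step is one *epoch* of minibatch gradient descent
  (default batch 128, Adam), not a single batch step: a full pass is a
  refinement of uniform strength regardless of dataset size, keeping
  iteration counts comparable across scales. Both batch size and the cap are
  configurable.
* Initialisation defaults to a supervised warm start on `Ds`. When the
  partial label group is not covered by the supervised one (the no-overlap
  scenario) the warm-up additionally uses a random labeling of `Dpl` drawn
  from the candidate sets — without it, labels never seen with supervision
  would start the alternation unscored. A pure random-labeling
  initialisation is also available.
* `mu` and `lambda` default to 1; `lambda = 0` provably reduces training to
  the supervised special case (tested bit-for-bit), as do singleton
  candidate sets.

## Classifier families

| family | score | hierarchical variant |
|--------|-------|----------------------|
| `pb_l` | `-||A x - p_c||^2`, learned linear embedding + one prototype per label | margin rescaling |
| `pb_nn` | same, embedding is a 2-hidden-layer tanh network | margin rescaling |
| `svm` | `w_c . x + b_c`, structured hinge | margin rescaling |
| `ksvm` | linear margin model on a random trigonometric feature map (Gaussian-kernel approximation, default 1024 features) | margin rescaling |
| `lr` | linear scores, softmax cross-entropy | — |
| `knn` | neighbour votes; a partially labeled neighbour contributes `1/|Y_i|` per candidate | tree-median vote |
| `rf`, `xgbm` | per-class probability | — |

The structured hinge is `max_{y' != y} max(0, Delta(y, y') + s(y') - s(y))`
with `Delta = 1` flat and `Delta = C[y, y']` hierarchical (margin
rescaling): mistakes towards distant branches of the lineage must be beaten
by a larger margin, and the training loss upper-bounds the average tree
dissimilarity between predicted and true labels. With unit off-diagonal `C`
the hierarchical loss is exactly the flat one — kept as a regression test.

Choices the reconstruction had to make: the prototype families use the same
margin-rescaled hinge as the margin models, with prototypes as free learned
parameters (small-Gaussian initialised) rather than class means; the kernel
approximation is the random trigonometric (Fourier) map; hierarchical kNN —
which has no canonical definition — predicts the label minimising the
expected tree distance to the neighbours' vote distribution, i.e. a tree
median. Ensembles have no margin structure to rescale, and logistic
regression is left flat; requesting a hierarchical variant of those families
is an error rather than a silent fallback.

`pb_nn` defaults to two hidden layers of width 128 and an embedding width of
64. On the 100-component feature spaces used throughout, 128-wide layers
train noticeably faster than wider ones with no measurable loss in accuracy;
depth and widths remain hyperparameters since the network overfits small
label sets (the documented remedy is reducing depth).

## The count simulator

`simulate_cells()` generates tree-structured scRNA-seq-like data:

* `g` genetic programs evolve as Gaussian random walks on the label tree
  (step sd 0.3, floored at 0.01), each node storing its segment-end state;
* a cell sits at a uniform position `u` along its label's segment
  (pseudotime = depth + `u`) and its program levels interpolate linearly
  from the parent's end state to its own label's — expression drifts
  continuously along the trajectory, so cells near a boundary are genuinely
  confusable with the adjacent label. This within-segment drift is what
  keeps lineage-resolved classification from being trivially clusterable,
  and without it every metric saturates;
* each gene loads on 1–3 programs (Gamma weights, normalised), with
  lognormal base expression (median 10 counts);
* counts are negative binomial with mean `m` and variance `m + alpha m^2`;
  `alpha = 0.1` is the low-noise and `0.5` the high-noise condition.

What it deliberately does not emulate: batch effects, doublets, explicit
zero inflation, library-size variation, or numerical parity with any
specific published simulator. Passing benchmarks on these data therefore
demonstrates that the training loops solve the partial-label problem under
realistic trajectory geometry and count noise — not that they are robust to
every artefact of real experiments; the real-data loaders (`read_expression`
and friends) exist for that use.

## Scenario generation

`split_scenario()` reproduces the benchmark protocol: overlap `o in {0, 1}`
between supervised and partial label groups (o = 0 splits the label set
uniformly into halves); a per-label 20% test reserve taken first (split
evenly between the two test sets when a label belongs to both groups);
`n` supervised samples per label (or a fraction `p` for real, unbalanced
data); 200 partial samples per label (or 80% of the remaining training
cells); candidate sets of size `k` drawn uniformly from per-label
co-occurrence pools of 15 labels sampled inside a tree-distance interval
`I`. Pools too small for `k - 1` distractors are a hard error — silently
widening `I` would corrupt the distance-controlled experiments. Every
random choice flows from the scenario seed; cut `i` of the protocol uses
seed `+ i`, and the whole pipeline is bit-reproducible from (config, seed).

## Problem sizes

The package's reduced benchmark (`benchmark_reduced_branches()`) uses a
depth-9 Branches tree — 55 labels, the same asymmetric topology as the
full-scale 253-label setting — with 500 genes, `g = 50`, `alpha = 0.1`, 280
cells per label, 20 supervised plus 200 partial training samples per label,
`I = (1, 15)`, and 5 cuts per scenario. At this size one PB-nn IRL fit takes
tens of seconds on a single core, so the three headline scenarios complete
in minutes while exhibiting the same qualitative regime as the full-scale
runs (near-ceiling prior-restricted precision, mid-0.8s unrestricted
precision). The training schedule at this scale is 30 warm-up epochs and up
to 40 refinement iterations with 512-sample batches at Adam step 3e-3 —
the labeling is typically stable well before the cap.

## Known limitations

* The exact kernel (dual) SVM is deliberately absent; `ksvm` is the
  primal random-feature approximation, usable under IRL.
* CV-based model selection scores partial folds by prior-restricted
  precision using the retained hidden labels — a simulation-only
  convenience; on real data without hidden truths the supervised folds
  alone drive selection.
* Hierarchies must be trees (single parent); ontologies with multiple
  parents are out of scope.
* `o` is implemented for the two benchmark values {0, 1}; the fractional
  overlap statistic is computed on outputs for verification only.
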