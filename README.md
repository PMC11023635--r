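# plcell — partial label learning for single-cell transcriptomic classification

Automated cell-type / lineage-stage annotation of scRNA-seq profiles usually
assumes a fully supervised training atlas. In practice annotation is often
*partial*: markers or a coarse reference narrow a cell down to a small set of
candidate labels, exactly one of which is correct. `plcell` implements
classification from such partially labeled data, for computational biologists
benchmarking annotation strategies and for machine-learning practitioners
studying candidate-label disambiguation with hierarchical label structure.

## The model

The training set is `D = Ds ∪ Dpl`: `l` supervised pairs `(xᵢ, yᵢ)` and `m`
partially labeled pairs `(xᵢ, Yᵢ)` with the true label hidden inside the
candidate set `Yᵢ` (|Yᵢ| = k). Every classifier exposes a per-label score and
predicts by argmax. Partial-label training minimises

    Ω(W) + (μ/l) Σ_Ds loss(f_W, xᵢ, yᵢ) + (λ/m) Σ_Dpl min_{ỹ∈Yᵢ} loss(f_W, xᵢ, ỹ)

by alternating (a) inference of the most likely candidate label
`ỹᵢ = argmax_{y∈Yᵢ} score(f_W, xᵢ, y)` and (b) refitting on the resulting
fully labeled view — one gradient epoch per iteration (**IRL**, for
prototype, margin, kernel-approximated and logistic models) or a full
from-scratch retrain (**IFR**, for tree ensembles). When the labels form a
lineage tree, the unit classification margin is rescaled by the tree
dissimilarity `C[y, y′]` (shortest-path edge count), so mistakes towards
distant branches cost more; kNN gets a tree-median vote. At test time
prediction is unrestricted or, when candidate information exists for test
cells too, restricted to `Yᵢ` — measured by `precision` and
`precision_with_prior` respectively.

The package also ships a tree-structured count simulator (genetic programs as
random walks on the label tree, interpolated along pseudotime within
segments, negative-binomial noise with variance `m + α·m²`), scenario
generators controlling label overlap `o`, candidate-set size `k` and the
tree-distance interval `I` of the distractors, and a cut/cross-validation
benchmarking protocol with paired-t significance flags. See the vignette in
`vignettes/partial-label-methods.Rmd` for the full methods account.

## Worked example

```r
library(plcell)

h   <- build_topology("branches", 4)                # 15-label lineage tree
ds  <- simulate_cells(h, g = 10, alpha = 0.1,
                      cells_per_label = 150, n_genes = 200, seed = 3)
cfg <- scenario_config(o = 1, n = 20, k = 2, interval = c(1, 5),
                       partial_per_label = 80, seed = 7)
scn   <- split_scenario(ds, cfg)
feats <- scenario_features(ds, scn, n_components = 50)

fit <- pll_fit(pll_model("pb_nn", labels = h$labels),
               training_data(scn, feats), method = "irl",
               config = train_config(seed = 5, warmup_epochs = 30,
                                     max_iterations = 60, learning_rate = 3e-3))
summary(fit)
#> <pll_fit> pb_nn (irl), 15 labels, 29 refinement iterations
#>   objective: 1.0099 -> 0.0453 over 29 iterations
#>   labeling changes (last 5 iters): 0 0 0 0 0
round(evaluate_fit(fit, scn, feats), 3)
#>        precision_s       precision_pl precision_pl_prior
#>              0.582              0.636              0.933
```

The objective trace shows the alternation converging to a stable labeling.
On this deliberately small 15-label trajectory the nonlinear prototype model
classifies ~60% of held-out cells exactly (chance is 1/15; adjacent segments
overlap by construction), and when a size-2 candidate set is available for a
test cell it picks the right one 93% of the time — the disambiguation regime
partial-label learning is designed for. 94.6% of the hidden training labels
were recovered (`mean(fit$state$labeling == scn$y_pl)`).

Real data enter through `read_expression()` (MatrixMarket + TSV),
`read_labels()` / `read_candidates()`, and `load_hierarchy()` (edge-list TSV
or Newick). `inst/cli/plcell.R` wraps simulation and benchmarking for shell
use (`simulate` / `benchmark` subcommands with `--config`, `--seed`,
`--out`).

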