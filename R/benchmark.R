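#' Reduced Branches benchmark of the nonlinear prototype classifier
#'
#' Runs the package's headline simulated experiment at desk scale: an
#' asymmetric Branches label tree of depth 9 (55 labels), 500 genes, 50
#' genetic programs, low negative-binomial noise (`alpha = 0.1`), 280 cells
#' per label. For each requested scenario (`o`, `k`; supervision fixed at 20
#' supervised plus 200 partially labeled training samples per label, close
#' distance interval `I = (1, 15)`) the protocol performs `n_cuts`
#' train/test cuts, trains the nonlinear prototype model (`pb_nn`) by
#' iterative refinement learning on each cut, and evaluates precision on the
#' supervised test set and plain/candidate-restricted precision on the
#' partial test set.
#'
#' The training schedule at this scale is 30 supervised warm-up epochs
#' followed by up to 40 refinement iterations (one 512-sample minibatch epoch
#' each, Adam step 3e-3); the inferred labeling is typically stable well
#' before the cap.
#'
#' @param seed master seed: the simulation uses a seed derived from it, cut
#'   `i` of a scenario uses scenario seed `+ i`
#' @param n_cuts train/test cuts per scenario (default 5)
#' @param scenarios list of `list(o =, k =)` settings
#' @param depth,cells_per_label,g,alpha,n_genes simulation parameters
#' @param n,partial_per_label,interval supervision parameters
#' @param n_components principal components of the feature space
#' @param config [train_config()] for the prototype network (seed field is
#'   overwritten per cut)
#' @return long data frame: `o`, `k`, `cut`, `metric`, `value`
#' @export
benchmark_reduced_branches <- function(seed = 1L, n_cuts = 5L,
    scenarios = list(list(o = 1, k = 2), list(o = 1, k = 4), list(o = 0, k = 2)),
    depth = 9L, cells_per_label = 280L, g = 50, alpha = 0.1, n_genes = 500L,
    n = 20L, partial_per_label = 200L, interval = c(1L, 15L),
    n_components = 100L,
    config = train_config(warmup_epochs = 30L, max_iterations = 40L,
                          learning_rate = 3e-3, batch_size = 512L,
                          track_objective = FALSE)) {
  h <- build_topology("branches", depth)
  ds <- simulate_cells(h, g = g, alpha = alpha,
                       cells_per_label = cells_per_label, n_genes = n_genes,
                       seed = derive_seed(seed, 1L))
  rows <- list()
  for (sc in scenarios) {
    for (cut in seq_len(n_cuts) - 1L) {
      cfg <- scenario_config(o = sc$o, n = n, k = sc$k, interval = interval,
                             partial_per_label = partial_per_label,
                             seed = derive_seed(seed, 50L + 10L * sc$o + sc$k) %%
                               2000000000L + cut)
      scn <- split_scenario(ds, cfg)
      feats <- scenario_features(ds, scn, n_components = n_components)
      tcfg <- config
      tcfg$seed <- derive_seed(cfg$seed, 9L)
      fit <- pll_fit(pll_model("pb_nn", labels = h$labels),
                     training_data(scn, feats), method = "irl", config = tcfg)
      ev <- evaluate_fit(fit, scn, feats)
      for (metric in names(ev))
        rows[[length(rows) + 1L]] <- data.frame(
          o = sc$o, k = sc$k, cut = cut, metric = metric, value = ev[[metric]])
    }
  }
  do.call(rbind, rows)
}

#' @rdname benchmark_reduced_branches
#' @param results data frame returned by `benchmark_reduced_branches`
#' @return `benchmark_summary`: mean value per scenario and metric
#' @export
benchmark_summary <- function(results) {
  agg <- stats::aggregate(value ~ o + k + metric, data = results, FUN = mean)
  agg[order(agg$o, agg$k, agg$metric), ]
}
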