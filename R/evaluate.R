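#' Classification precision
#'
#' Fraction of predictions equal to the true label.
#'
#' @param predictions character vector of predicted labels
#' @param truths character vector of true labels, same length
#' @return fraction in `[0, 1]`
#' @export
precision <- function(predictions, truths) {
  if (!length(predictions)) stop("empty prediction vector")
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  mean(predictions == truths)
}

#' Precision of candidate-restricted prediction
#'
#' Precision when each test sample's prediction is restricted to its
#' candidate set (the "prior"). Defined for partially labeled test samples
#' whose hidden true label was retained for evaluation; every candidate set
#' must contain its sample's hidden label.
#'
#' @param model a trained `pll_scorer`
#' @param X partial-test feature matrix
#' @param candidates list of candidate sets, one per row
#' @param truths hidden true labels
#' @return fraction in `[0, 1]`
#' @export
precision_with_prior <- function(model, X, candidates, truths) {
  ok <- mapply(function(s, y) y %in% s, candidates, truths)
  if (!all(ok))
    stop("candidate set misses its hidden label for sample(s): ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  precision(predict_labels(model, X, prior = candidates), truths)
}

#' Evaluate a fitted model on a scenario's test sets
#'
#' @param fit a `pll_fit` (or bare `pll_scorer`)
#' @param scn the `pll_scenario`
#' @param feats feature matrices from [scenario_features()]
#' @return named numeric vector: `precision_s` (supervised test set, no
#'   prior), `precision_pl` (partial test set, no prior) and
#'   `precision_pl_prior` (partial test set, prediction within candidates)
#' @export
evaluate_fit <- function(fit, scn, feats) {
  model <- if (inherits(fit, "pll_fit")) fit$model else fit
  out <- c(precision_s = NA_real_, precision_pl = NA_real_,
           precision_pl_prior = NA_real_)
  if (length(scn$ys_test))
    out["precision_s"] <- precision(predict_labels(model, feats$Xs_test),
                                    scn$ys_test)
  if (length(scn$y_pl_test)) {
    out["precision_pl"] <- precision(predict_labels(model, feats$Xpl_test),
                                     scn$y_pl_test)
    out["precision_pl_prior"] <- precision_with_prior(
      model, feats$Xpl_test, scn$cand_pl_test, scn$y_pl_test)
  }
  out
}

#' Run the multi-cut benchmark protocol for one experimental setting
#'
#' For each of `n_cuts` cuts (scenario seeds `seed + 0 .. seed + n_cuts-1`):
#' generate the scenario split, fit every method on the training split —
#' selecting among its candidate configurations by `cv_folds`-fold
#' cross-validation on the training data when more than one is given — and
#' evaluate both metrics on the supervised and partial test sets. Cut values
#' are averaged per method and metric.
#'
#' CV selection scores a configuration by held-out correctness: plain
#' precision on supervised folds, candidate-restricted precision on partial
#' folds (the simulation retains hidden labels, making the latter computable).
#'
#' @param ds an `expression_dataset`
#' @param cfg a [scenario_config()]; its seed anchors the cut seeds
#' @param methods named list; each element is a list with `model` (an
#'   untrained [pll_model()]), `method` (`"irl"`, `"ifr"` or
#'   `"supervised"`), optional `config` (a [train_config()]) and optional
#'   `grid` (list of named lists of `train_config` overrides to select by CV)
#' @param n_cuts number of train/test cuts (default 5)
#' @param cv_folds folds for hyperparameter selection (default 5)
#' @param n_components principal components of the feature space
#' @return a `benchmark_row`: list with `results` (long data frame: cut,
#'   method, metric, value, seed) and `means` (method x metric matrix)
#' @export
run_protocol <- function(ds, cfg, methods, n_cuts = 5L, cv_folds = 5L,
                         n_components = 100L) {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  rows <- list()
  for (cut in seq_len(n_cuts) - 1L) {
    cfg_cut <- cfg
    cfg_cut$seed <- cfg$seed + cut
    scn <- split_scenario(ds, cfg_cut)
    feats <- scenario_features(ds, scn, n_components = n_components)
    data <- training_data(scn, feats)
    for (nm in names(methods)) {
      sp <- methods[[nm]]
      base <- sp$config %||% train_config()
      base$seed <- derive_seed(cfg_cut$seed, 300L + match(nm, names(methods)))
      grid <- sp$grid %||% list()
      chosen <- if (length(grid) > 1L)
        select_by_cv(sp, data, scn, base, grid, cv_folds) else
        if (length(grid) == 1L) merge_config(base, grid[[1]]) else base
      fit <- pll_fit(sp$model, data, method = sp$method, config = chosen)
      ev <- evaluate_fit(fit, scn, feats)
      for (metric in names(ev))
        rows[[length(rows) + 1L]] <- data.frame(
          cut = cut, method = nm, metric = metric, value = ev[[metric]],
          seed = cfg_cut$seed, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  means <- tapply(results$value, list(results$method, results$metric), mean)
  structure(list(results = results, means = means, config = cfg),
            class = "benchmark_row")
}

merge_config <- function(base, overrides) {
  out <- utils::modifyList(unclass(base), overrides)
  class(out) <- "train_config"
  out
}

# hyperparameter selection by stratified k-fold CV on the training split
select_by_cv <- function(sp, data, scn, base, grid, cv_folds) {
  n_s <- length(data$ys); n_pl <- if (is.null(data$Xpl)) 0L else nrow(data$Xpl)
  fold_s <- fold_assign(data$ys, cv_folds, derive_seed(base$seed, 31L))
  fold_pl <- if (n_pl) fold_assign(scn$y_pl, cv_folds, derive_seed(base$seed, 32L))
  scores <- vapply(grid, function(g) {
    cfg <- merge_config(base, g)
    acc <- 0; tot <- 0
    for (f in seq_len(cv_folds)) {
      tr_s <- fold_s != f; tr_pl <- if (n_pl) fold_pl != f else logical(0)
      d_tr <- pll_train_data(
        data$Xs[tr_s, , drop = FALSE], data$ys[tr_s],
        if (n_pl && any(tr_pl)) data$Xpl[tr_pl, , drop = FALSE],
        if (n_pl && any(tr_pl)) data$candidates[tr_pl])
      fit <- pll_fit(sp$model, d_tr, method = sp$method, config = cfg)
      if (any(!tr_s)) {
        pred <- predict(fit, data$Xs[!tr_s, , drop = FALSE])
        acc <- acc + sum(pred == data$ys[!tr_s]); tot <- tot + sum(!tr_s)
      }
      if (n_pl && any(!tr_pl)) {
        pred <- predict(fit, data$Xpl[!tr_pl, , drop = FALSE],
                        prior = data$candidates[!tr_pl])
        acc <- acc + sum(pred == scn$y_pl[!tr_pl]); tot <- tot + sum(!tr_pl)
      }
    }
    acc / max(tot, 1)
  }, 0)
  merge_config(base, grid[[which.max(scores)]])
}

fold_assign <- function(y, k, seed) {
  f <- integer(length(y))
  with_seed(seed, {
    for (lab in unique(y)) {
      idx <- which(y == lab)
      idx <- idx[sample.int(length(idx))]
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  f
}

#' Best-method flag by paired t-test
#'
#' Mirrors the benchmark's significance rule: within each model family
#' (prototype, margin, nearest-neighbour, ...) the best variant by mean is
#' selected; the top two family representatives are compared by a paired
#' t-test on their per-cut values; the winner is flagged iff `p < p_threshold`.
#'
#' @param values matrix of per-cut values (rows = cuts, columns = methods)
#' @param families character vector mapping each column to a family; by
#'   default derived from the column name prefix (`pb_nn` -> `pb`,
#'   `ksvm` -> `svm`)
#' @param p_threshold significance level, default 0.1
#' @return list with `best` (method name), `runner_up`, `p_value`, and
#'   `flagged` (logical: best significantly better)
#' @export
significance <- function(values, families = NULL, p_threshold = 0.1) {
  if (ncol(values) < 2L) stop("need at least two methods to compare")
  if (is.null(families)) families <- method_family(colnames(values))
  means <- colMeans(values)
  reps <- vapply(split(seq_along(means), families),
                 function(ix) ix[which.max(means[ix])], 0L)
  reps <- reps[order(means[reps], decreasing = TRUE)]
  if (length(reps) < 2L) reps <- order(means, decreasing = TRUE)[1:2]
  a <- values[, reps[1]]; b <- values[, reps[2]]
  d <- a - b
  # an (essentially) constant difference is a degenerate paired t:
  # certain win, or a tie when the constant is ~0
  p <- if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) 1 else 0
  } else {
    tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
             error = function(e) if (abs(mean(d)) <= 1e-12) 1 else 0)
  }
  list(best = colnames(values)[reps[1]],
       runner_up = colnames(values)[reps[2]],
       p_value = p,
       flagged = isTRUE(p < p_threshold))
}

method_family <- function(nm) {
  fam <- sub("^hier_", "", nm)
  fam[grepl("^pb", fam)] <- "pb"
  fam[grepl("svm", fam)] <- "svm"
  fam[grepl("knn", fam)] <- "knn"
  fam
}
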