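#' Training configuration
#'
#' Hyperparameters of the alternating label-inference / refit training loops.
#'
#' @param mu weight of the supervised term of the objective
#' @param lambda weight of the partial-label term; `0` makes training ignore
#'   the partially labeled samples entirely
#' @param l2 L2 regularisation strength on weight matrices (`Omega(W)`)
#' @param learning_rate Adam step size for the gradient families
#' @param batch_size minibatch size of one refinement epoch
#' @param epochs full-training epochs for `method = "supervised"` and for
#'   each from-scratch fit inside iterative full retraining
#' @param warmup_epochs supervised epochs run before the first label
#'   inference of iterative refinement
#' @param max_iterations cap on refinement iterations (`NULL`: 300 for IRL,
#'   10 for IFR)
#' @param patience stop once the inferred labeling has been unchanged for
#'   this many consecutive refinement iterations (IRL; IFR stops at the first
#'   labeling fixed point)
#' @param init_mode `"supervised_warmstart"` (train on the supervised subset
#'   first; partially labeled samples are given random candidate labels for
#'   the warm-up only when their label group is not covered by the supervised
#'   one) or `"random_labeling"` (warm-up on supervised plus randomly
#'   labeled partial samples)
#' @param optimizer `"adam"` (default) or `"sgd"` (plain constant-step
#'   gradient descent; with a small step the partial objective decreases
#'   essentially monotonically for the convex families)
#' @param seed integer; drives parameter initialisation, batch shuffling and
#'   random labelings
#' @param track_objective record the partial-label objective at every
#'   iteration
#' @return a `train_config` list
#' @export
train_config <- function(mu = 1, lambda = 1, l2 = 1e-4, learning_rate = 1e-2,
                         batch_size = 128L, epochs = 100L, warmup_epochs = 50L,
                         max_iterations = NULL, patience = 5L,
                         init_mode = c("supervised_warmstart", "random_labeling"),
                         optimizer = c("adam", "sgd"),
                         seed = 1L, track_objective = TRUE) {
  stopifnot(mu >= 0, lambda >= 0, learning_rate >= 0)
  structure(list(mu = mu, lambda = lambda, l2 = l2,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 max_iterations = max_iterations,
                 patience = patience,
                 init_mode = match.arg(init_mode),
                 optimizer = match.arg(optimizer),
                 seed = as.integer(seed),
                 track_objective = isTRUE(track_objective)),
            class = "train_config")
}

#' Bundle training matrices for partial-label fitting
#'
#' @param Xs supervised feature matrix (may have zero rows)
#' @param ys supervised labels
#' @param Xpl partially labeled feature matrix (optional)
#' @param candidates list of candidate-label sets, one per row of `Xpl`
#' @return a `pll_data` list
#' @export
pll_train_data <- function(Xs, ys, Xpl = NULL, candidates = NULL) {
  if (nrow(Xs) != length(ys)) stop("Xs/ys length mismatch")
  if (!is.null(Xpl)) {
    if (is.null(candidates) || length(candidates) != nrow(Xpl))
      stop("one candidate set per partially labeled sample required")
    if (any(lengths(candidates) == 0L)) stop("empty candidate set")
  }
  structure(list(Xs = Xs, ys = ys, Xpl = Xpl, candidates = candidates),
            class = "pll_data")
}

#' @rdname pll_train_data
#' @param scn a `pll_scenario`
#' @param feats feature matrices from [scenario_features()]
#' @export
training_data <- function(scn, feats) {
  pll_train_data(feats$Xs, scn$ys, feats$Xpl, scn$cand_pl)
}

#' Infer the most likely candidate label for each partially labeled sample
#'
#' The labeling step of the alternating algorithms: for every sample the
#' candidate label with the highest current score, ties broken towards the
#' smallest label index.
#'
#' @param model a trained `pll_scorer`
#' @param X partially labeled feature matrix
#' @param candidates list of candidate-label sets, one per row
#' @return character vector of inferred labels, each inside its candidate set
#' @export
infer_candidates <- function(model, X, candidates) {
  S <- score_matrix(model, X)
  vapply(seq_len(nrow(X)), function(i) {
    idx <- sort(label_index(model, candidates[[i]]))
    model$labels[idx[argmax1(S[i, idx])]]
  }, "")
}

#' Partial-label training objective
#'
#' `Omega(W) + (mu/l) * sum of supervised losses + (lambda/m) * sum over
#' partially labeled samples of the minimum loss over their candidate set`.
#' The per-sample minimum is exact (the objective is separable across
#' samples).
#'
#' @param model a trained `pll_scorer`
#' @param data a [pll_train_data()]
#' @param cfg a [train_config()]
#' @return scalar objective value
#' @export
partial_objective <- function(model, data, cfg) {
  val <- omega_value(model, cfg$l2)
  if (length(data$ys))
    val <- val + cfg$mu * mean(supervised_loss(model, data$Xs, data$ys))
  if (!is.null(data$Xpl) && nrow(data$Xpl)) {
    S <- score_matrix(model, data$Xpl)
    Delta <- delta_matrix(model)
    kmax <- max(lengths(data$candidates))
    best <- rep(Inf, nrow(data$Xpl))
    for (j in seq_len(kmax)) {
      has <- lengths(data$candidates) >= j
      yj <- vapply(data$candidates[has], function(s) sort(s)[j], "")
      lj <- loss_from_scores(model, S[has, , drop = FALSE],
                             label_index(model, yj), Delta)
      best[has] <- pmin(best[has], lj)
    }
    val <- val + cfg$lambda * mean(best)
  }
  val
}

# labeled view weights: mu/l on supervised rows, lambda/m on partial rows
view_weights <- function(cfg, l, m) {
  c(if (l) rep(cfg$mu / l, l), if (m) rep(cfg$lambda / m, m))
}

random_labeling <- function(candidates, seed) {
  with_seed(seed, vapply(candidates, function(s)
    if (length(s) == 1L) s else s[sample.int(length(s), 1L)], ""))
}

#' Iterative refinement learning
#'
#' Alternates (a) inference of the most likely candidate label for every
#' partially labeled sample under the current model and (b) one refinement
#' epoch of minibatch gradient descent on the resulting fully labeled view of
#' the data, weighted `mu/l` (supervised) and `lambda/m` (partial). Training
#' stops when the inferred labeling has not changed for `patience`
#' consecutive iterations or after `max_iterations`. Only gradient-trainable
#' families can be refined this way.
#'
#' @param model an untrained gradient-trainable `pll_scorer`
#' @param data a [pll_train_data()]
#' @param cfg a [train_config()]
#' @return list with `model` (trained) and `state` (iterations run,
#'   inferred `labeling`, `objective` trace, `changes` per iteration)
#' @export
irl_fit <- function(model, data, cfg = train_config()) {
  if (!model$trainable_by_gradient)
    stop("family '", model$family, "' cannot be trained by gradient refinement")
  if (is.null(data$Xpl) || !nrow(data$Xpl))
    stop("no partially labeled samples; use the supervised method instead")
  max_iter <- cfg$max_iterations %||% 300L
  l <- length(data$ys); m <- nrow(data$Xpl)
  model <- init_params(model, ncol(data$Xpl), derive_seed(cfg$seed, 11L))

  covered <- all(unique(unlist(data$candidates)) %in% data$ys)
  ytil <- NULL
  use_random <- cfg$init_mode == "random_labeling" ||
    (!covered && cfg$lambda > 0) || l == 0L
  if (use_random) ytil <- random_labeling(data$candidates, derive_seed(cfg$seed, 14L))

  # warm-up: supervised subset, plus randomly labeled partial samples when
  # those are needed to cover the label set
  if (cfg$warmup_epochs > 0L) {
    if (!is.null(ytil) && cfg$lambda > 0) {
      Xw <- rbind(data$Xs, data$Xpl)
      yw <- c(data$ys, ytil)
      ww <- view_weights(cfg, l, m)
    } else { Xw <- data$Xs; yw <- data$ys; ww <- view_weights(cfg, l, 0L) }
    if (length(yw))
      model <- refit_epochs(model, Xw, label_index(model, yw), ww, cfg,
                            n_epochs = cfg$warmup_epochs,
                            seed = derive_seed(cfg$seed, 12L))
  }

  objective <- numeric(0); changes <- integer(0)
  streak <- 0L; t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    ynew <- infer_candidates(model, data$Xpl, data$candidates)
    ch <- if (is.null(ytil)) NA_integer_ else sum(ynew != ytil)
    changes[t] <- ch
    streak <- if (!is.na(ch) && ch == 0L) streak + 1L else 0L
    ytil <- ynew
    if (streak >= cfg$patience) { t <- t - 1L; break }
    if (cfg$lambda > 0) {
      Xv <- rbind(data$Xs, data$Xpl); yv <- c(data$ys, ytil)
      wv <- view_weights(cfg, l, m)
    } else { Xv <- data$Xs; yv <- data$ys; wv <- view_weights(cfg, l, 0L) }
    model <- refit_epochs(model, Xv, label_index(model, yv), wv, cfg,
                          n_epochs = 1L, seed = derive_seed(cfg$seed, 100L + t))
    if (cfg$track_objective) objective[t] <- partial_objective(model, data, cfg)
  }
  list(model = model,
       state = list(iterations = t, labeling = ytil,
                    objective = objective, changes = changes))
}

#' Iterative full retraining
#'
#' The variant of the alternating scheme for models that cannot be warm
#' started (tree ensembles, exact kernel machines): at every iteration a
#' fresh model is trained to convergence on the current fully labeled view,
#' then the labeling is re-inferred. Stops at a labeling fixed point or after
#' `max_iterations` (default 10). If a maximally expressive model reproduces
#' its initial labeling exactly at the first iteration — i.e. it interpolates
#' any labeling, so the alternation can never move — a warning is raised.
#'
#' @param factory zero-argument function returning a fresh untrained
#'   `pll_scorer` (or a `pll_scorer`, reset and refitted at each iteration)
#' @inheritParams irl_fit
#' @return list with `model` and `state` as in [irl_fit()]
#' @export
ifr_fit <- function(factory, data, cfg = train_config()) {
  if (inherits(factory, "pll_scorer")) {
    proto <- strip_fit(factory)
    factory <- function() proto
  }
  if (is.null(data$Xpl) || !nrow(data$Xpl))
    stop("no partially labeled samples; use the supervised method instead")
  max_iter <- cfg$max_iterations %||% 10L
  l <- length(data$ys); m <- nrow(data$Xpl)
  ytil <- random_labeling(data$candidates, derive_seed(cfg$seed, 21L))
  objective <- numeric(0); changes <- integer(0)
  model <- NULL; t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    model <- factory()
    cfg_t <- cfg; cfg_t$seed <- derive_seed(cfg$seed, 200L + t)
    model <- fit_full(model, rbind(data$Xs, data$Xpl), c(data$ys, ytil), cfg_t)
    ynew <- infer_candidates(model, data$Xpl, data$candidates)
    changes[t] <- sum(ynew != ytil)
    if (cfg$track_objective) objective[t] <- partial_objective(model, data, cfg)
    if (t == 1L && changes[t] == 0L &&
        any(lengths(data$candidates) > 1L) &&   # singletons cannot move anyway
        all(predict_labels(model, data$Xpl) == ytil))
      warning("degenerate fixed point: the model interpolates its initial ",
              "random labeling; restrict the model's expressivity",
              call. = FALSE)
    fixed <- changes[t] == 0L
    ytil <- ynew
    if (fixed) break
  }
  list(model = model,
       state = list(iterations = t, labeling = ytil,
                    objective = objective, changes = changes))
}

strip_fit <- function(model) {
  model$params <- NULL; model$store <- NULL; model$fitobj <- NULL
  model$adam <- NULL; model$rff <- NULL
  model
}

#' Fit a partial-label classifier
#'
#' The central fitting function. `method = "irl"` runs iterative refinement
#' learning (gradient families), `"ifr"` iterative full retraining (any
#' family), `"supervised"` plain supervised training on the supervised subset
#' only. For `knn` the "fit" is storage of the training set: supervised
#' samples with their label and, under `"ifr"`/`"supervised"` with partial
#' data present, partially labeled samples with fractional votes spread over
#' their candidate sets.
#'
#' @param model an untrained `pll_scorer` from [pll_model()]
#' @param data a [pll_train_data()]
#' @param method `"irl"`, `"ifr"` or `"supervised"`
#' @param config a [train_config()]
#' @return a `pll_fit` object with `model`, `method`, `config` and the
#'   refinement `state`
#' @export
pll_fit <- function(model, data, method = c("irl", "ifr", "supervised"),
                    config = train_config()) {
  method <- match.arg(method)
  if (model$family == "knn" && method != "irl") {
    # storage-only fit: supervised labels plus candidate votes if available
    y <- if (!is.null(data$Xpl) && method != "supervised")
      c(as.list(data$ys), data$candidates) else as.list(data$ys)
    X <- if (!is.null(data$Xpl) && method != "supervised")
      rbind(data$Xs, data$Xpl) else data$Xs
    trained <- fit_full(model, X, y, config)
    state <- list(iterations = 0L, labeling = NULL,
                  objective = numeric(0), changes = integer(0))
  } else {
    res <- switch(method,
      irl = irl_fit(model, data, config),
      ifr = ifr_fit(model, data, config),
      supervised = list(model = fit_full(model, data$Xs, data$ys, config),
                        state = list(iterations = config$epochs,
                                     labeling = NULL,
                                     objective = numeric(0),
                                     changes = integer(0))))
    trained <- res$model; state <- res$state
  }
  structure(list(model = trained, method = method, config = config,
                 state = state, labels = model$labels),
            class = "pll_fit")
}

#' @export
print.pll_fit <- function(x, ...) {
  cat(sprintf("<pll_fit> %s (%s%s), %d labels, %d refinement iterations\n",
              x$model$family, x$method,
              if (x$model$hierarchical) ", hierarchical" else "",
              length(x$labels), x$state$iterations))
  invisible(x)
}

#' @export
summary.pll_fit <- function(object, ...) {
  print(object)
  st <- object$state
  if (length(st$objective))
    cat(sprintf("  objective: %.4f -> %.4f over %d iterations\n",
                st$objective[1], st$objective[length(st$objective)],
                length(st$objective)))
  if (length(st$changes))
    cat(sprintf("  labeling changes (last 5 iters): %s\n",
                paste(utils::tail(st$changes, 5), collapse = " ")))
  invisible(object)
}

#' Predict labels from a fitted partial-label classifier
#'
#' Without `prior`, predicts over the full label set; with `prior` (a list of
#' candidate-label sets, one per row of `newdata`) the prediction is
#' restricted to each sample's candidates.
#'
#' @param object a `pll_fit`
#' @param newdata feature matrix
#' @param prior optional list of candidate-label character vectors
#' @param ... unused
#' @return character vector of predicted labels
#' @export
predict.pll_fit <- function(object, newdata, prior = NULL, ...) {
  predict_labels(object$model, newdata, prior = prior)
}
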