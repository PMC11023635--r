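labs4 <- c("a", "b", "c", "d")

test_that("candidate inference is the restricted argmax", {
  m <- mock_scorer(c("a", "b", "c"))
  # scores (0.9, 0.1, 0.5), candidates {b, c} -> c
  expect_equal(infer_candidates(m, matrix(c(0.9, 0.1, 0.5), 1),
                                list(c("b", "c"))), "c")
  # singleton candidate wins regardless of scores
  expect_equal(infer_candidates(m, matrix(c(9, -9, 0), 1), list("b")), "b")
  # brute-force oracle over random score vectors and candidate sets
  m4 <- mock_scorer(labs4)
  withr::with_seed(12, {
    for (i in 1:100) {
      S <- matrix(rnorm(4), 1, 4)
      cand <- sort(sample(labs4, sample(1:4, 1)))
      got <- infer_candidates(m4, S, list(cand))
      best <- cand[which.max(S[1, match(cand, labs4)])]
      expect_identical(got, best)
    }
  })
})

test_that("prediction with and without prior follows the restricted argmax", {
  m <- mock_scorer(labs4)
  withr::with_seed(13, {
    for (i in 1:50) {
      S <- matrix(rnorm(4), 1, 4)
      expect_identical(predict_labels(m, S, prior = list("c")), "c")
      expect_identical(predict_labels(m, S, prior = list(labs4)),
                       predict_labels(m, S))
      pr <- sort(sample(labs4, 2))
      expect_identical(predict_labels(m, S, prior = list(pr)),
                       pr[which.max(S[1, match(pr, labs4)])])
    }
  })
  expect_error(predict_labels(m, matrix(0, 1, 4), prior = list("zz")),
               "unknown label")
  expect_error(predict_labels(m, matrix(0, 1, 4), prior = list(character(0))),
               "empty prior")
})

test_that("the partial objective reduces correctly and matches brute force", {
  m <- mock_scorer(labs4)
  cfg <- train_config(mu = 1, lambda = 1, l2 = 0)
  withr::with_seed(14, {
    Xs <- matrix(rnorm(12 * 4), 12, 4)
    ys <- sample(labs4, 12, replace = TRUE)
    Xpl <- matrix(rnorm(5 * 4), 5, 4)
    cand <- replicate(5, sort(sample(labs4, 2)), simplify = FALSE)
  })
  # no partial data: the plain supervised objective
  d0 <- pll_train_data(Xs, ys)
  expect_equal(partial_objective(m, d0, cfg),
               mean(supervised_loss(m, Xs, ys)))
  # singleton candidates: supervised objective on the union (equal weights)
  dsing <- pll_train_data(Xs, ys, Xpl, as.list(ys[1:5]))
  expect_equal(partial_objective(m, dsing, cfg),
               mean(supervised_loss(m, Xs, ys)) +
                 mean(supervised_loss(m, Xpl, ys[1:5])))
  # per-sample min equals the global min over all labelings (separable terms)
  dpl <- pll_train_data(Xs, ys, Xpl, cand)
  labelings <- expand.grid(lapply(cand, identity), stringsAsFactors = FALSE)
  brute <- min(apply(labelings, 1, function(lab)
    mean(supervised_loss(m, Xpl, unname(unlist(lab))))))
  expect_equal(partial_objective(m, dpl, cfg),
               mean(supervised_loss(m, Xs, ys)) + brute)
  expect_error(pll_train_data(Xs, ys, Xpl, c(cand[-5], list(character(0)))),
               "empty candidate")
})

test_that("IRL recovers hidden labels on separable data and stays in-candidate", {
  toy <- gaussian_partial_toy(seed = 42)
  m <- pll_model("svm", labels = toy$h$labels)
  res <- irl_fit(m, toy$data, fast_cfg(seed = 7))
  expect_true(all(mapply(`%in%`, res$state$labeling, toy$data$candidates)))
  expect_gte(mean(res$state$labeling == toy$y_hidden), 0.99)
  # the objective trace is monitored and finite
  expect_true(all(is.finite(res$state$objective)))
})

test_that("the partial objective is near-monotone under small-step descent", {
  toy <- gaussian_partial_toy(seed = 43)
  for (fam in c("svm", "lr")) {
    res <- irl_fit(pll_model(fam, labels = toy$h$labels), toy$data,
                   fast_cfg(seed = 3, optimizer = "sgd", learning_rate = 1e-4,
                            warmup_epochs = 40, max_iterations = 25,
                            batch_size = 1000))   # full-batch: true gradient
    obj <- res$state$objective
    expect_lt(obj[length(obj)], obj[1])
    if (fam == "lr")                 # smooth loss: monotone descent
      expect_true(all(diff(obj) <= 1e-6))
    else                             # hinge subgradients may oscillate
      expect_gte(mean(diff(obj) <= 1e-6), 0.5)
  }
})

test_that("a frozen model never changes its inferred labeling", {
  toy <- gaussian_partial_toy(seed = 5)
  m <- pll_model("pb_l", labels = toy$h$labels)
  res <- irl_fit(m, toy$data, fast_cfg(seed = 2, learning_rate = 0,
                                       max_iterations = 8, patience = 3))
  expect_true(all(res$state$changes[-1] == 0, na.rm = TRUE))
  # stopped by the patience rule, well before the iteration cap
  expect_lte(res$state$iterations, 4)
})

test_that("lambda = 0 makes refinement identical to supervised training", {
  toy <- gaussian_partial_toy(seed = 9)
  cfg <- fast_cfg(seed = 3, lambda = 0, max_iterations = 10, patience = Inf,
                  track_objective = FALSE)
  m <- pll_model("svm", labels = toy$h$labels)
  res <- irl_fit(m, toy$data, cfg)
  # supervised arm: same init, warm-up and epoch schedule on Ds only
  m2 <- plcell:::init_params(pll_model("svm", labels = toy$h$labels),
                             ncol(toy$data$Xs), plcell:::derive_seed(3L, 11L))
  yidx <- match(toy$data$ys, toy$h$labels)
  w <- rep(cfg$mu / length(yidx), length(yidx))
  m2 <- plcell:::refit_epochs(m2, toy$data$Xs, yidx, w, cfg,
                              n_epochs = cfg$warmup_epochs,
                              seed = plcell:::derive_seed(3L, 12L))
  for (t in seq_len(res$state$iterations))
    m2 <- plcell:::refit_epochs(m2, toy$data$Xs, yidx, w, cfg, n_epochs = 1,
                                seed = plcell:::derive_seed(3L, 100L + t))
  expect_identical(res$model$params, m2$params)
})

test_that("singleton candidate sets reduce IRL to supervised training", {
  toy <- gaussian_partial_toy(seed = 11, k = 1)
  cfg <- fast_cfg(seed = 6, max_iterations = 10, track_objective = FALSE)
  m <- pll_model("pb_l", labels = toy$h$labels)
  res <- irl_fit(m, toy$data, cfg)
  # after the first inference the labeling never changes
  expect_true(all(res$state$changes[-1] == 0, na.rm = TRUE))
  # supervised arm with the matched schedule on the fully labeled union
  m2 <- plcell:::init_params(pll_model("pb_l", labels = toy$h$labels),
                             ncol(toy$data$Xs), plcell:::derive_seed(6L, 11L))
  Xv <- rbind(toy$data$Xs, toy$data$Xpl)
  yv <- c(toy$data$ys, toy$y_hidden)
  yidx <- match(yv, toy$h$labels)
  l <- length(toy$data$ys); mpl <- nrow(toy$data$Xpl)
  w <- c(rep(cfg$mu / l, l), rep(cfg$lambda / mpl, mpl))
  m2 <- plcell:::refit_epochs(m2, toy$data$Xs, yidx[seq_len(l)], w[seq_len(l)],
                              cfg, n_epochs = cfg$warmup_epochs,
                              seed = plcell:::derive_seed(6L, 12L))
  for (t in seq_len(res$state$iterations))
    m2 <- plcell:::refit_epochs(m2, Xv, yidx, w, cfg, n_epochs = 1,
                                seed = plcell:::derive_seed(6L, 100L + t))
  expect_identical(res$model$params, m2$params)
})

test_that("IFR converges on separable data and reduces for singletons", {
  toy <- gaussian_partial_toy(seed = 21)
  fac <- function() pll_model("rf", labels = toy$h$labels, ntree = 30,
                              maxnodes = 8)
  res <- ifr_fit(fac, toy$data, train_config(seed = 2, max_iterations = 6,
                                             track_objective = FALSE))
  expect_gte(mean(res$state$labeling == toy$y_hidden), 0.95)
  # singletons: the labeling is fixed from the start, one iteration suffices
  toy1 <- gaussian_partial_toy(seed = 22, k = 1)
  res1 <- ifr_fit(function() pll_model("rf", labels = toy1$h$labels,
                                       ntree = 30, maxnodes = 8),
                  toy1$data, train_config(seed = 2, track_objective = FALSE))
  expect_equal(res1$state$iterations, 1L)
  expect_identical(res1$state$labeling, toy1$y_hidden)
})

test_that("an interpolating learner triggers the degenerate fixed-point warning", {
  toy <- gaussian_partial_toy(seed = 30, n_partial = 20)
  onenn <- function() pll_model("knn", labels = toy$h$labels, k_nn = 1)
  expect_warning(
    res <- ifr_fit(onenn, toy$data, train_config(seed = 4,
                                                 track_objective = FALSE)),
    "degenerate fixed point")
  expect_equal(res$state$iterations, 1L)
})

test_that("partial-only labels receive nonzero scores after o = 0 training", {
  # supervised labels {s1, s2}, partial-only labels {s3, s4}
  h <- build_topology("linear", 4)
  withr::with_seed(33, {
    centers <- c(0, 4, 8, 12)
    Xs <- matrix(rnorm(30, rep(centers[1:2], each = 15), 0.4), ncol = 1)
    ys <- rep(h$labels[1:2], each = 15)
    Xpl <- matrix(rnorm(60, rep(centers[3:4], each = 30), 0.4), ncol = 1)
    hidden <- rep(h$labels[3:4], each = 30)
  })
  cand <- lapply(hidden, function(y) sort(c(y, setdiff(h$labels[3:4], y))))
  data <- pll_train_data(Xs, ys, Xpl, cand)
  res <- irl_fit(pll_model("svm", labels = h$labels), data,
                 fast_cfg(seed = 10, max_iterations = 25))
  S <- score_matrix(res$model, Xpl)
  expect_true(all(is.finite(S[, 3:4])))
  expect_true(any(S[, 3:4] != 0))
  # and those labels are actually predicted on their own territory
  expect_gte(mean(predict_labels(res$model, Xpl) %in% h$labels[3:4]), 0.9)
})

test_that("pll_fit wraps the loops with working methods and predict", {
  toy <- gaussian_partial_toy(seed = 40)
  fit <- pll_fit(pll_model("pb_l", labels = toy$h$labels), toy$data,
                 method = "irl", config = fast_cfg(seed = 1))
  expect_s3_class(fit, "pll_fit")
  expect_output(print(fit), "pll_fit")
  expect_output(summary(fit), "labeling changes")
  pred <- predict(fit, toy$data$Xpl)
  expect_gte(mean(pred == toy$y_hidden), 0.95)
  pred_prior <- predict(fit, toy$data$Xpl, prior = toy$data$candidates)
  expect_gte(mean(pred_prior == toy$y_hidden), mean(pred == toy$y_hidden))
  sup <- pll_fit(pll_model("svm", labels = toy$h$labels), toy$data,
                 method = "supervised", config = fast_cfg(seed = 1))
  expect_gte(mean(predict(sup, toy$data$Xs) == toy$data$ys), 0.95)
  knn_fit <- pll_fit(pll_model("knn", labels = toy$h$labels), toy$data,
                     method = "ifr")
  expect_gte(mean(predict(knn_fit, toy$data$Xpl) == toy$y_hidden), 0.9)
  expect_error(pll_fit(pll_model("rf", labels = toy$h$labels), toy$data,
                       method = "irl"),
               "gradient")
})
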