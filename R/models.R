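#' Construct a classifier for (hierarchical) partial-label learning
#'
#' All classifiers obey one contract: they expose a score `score(x, c)` for
#' every label `c`, prediction is the argmax of the scores (ties broken
#' towards the smallest label index), and the score is defined for every
#' label — including labels that never occur with full supervision, which is
#' what lets partial-label training cover them.
#'
#' Families:
#' * `pb_l` / `pb_nn` — prototype-based: a linear (resp. multilayer tanh
#'   network) embedding of the input and one learned prototype per label;
#'   `score(x, c) = -||phi(x) - p_c||^2`. Trained with a structured hinge.
#' * `svm` — linear max-margin classifier, one weight vector per label,
#'   structured hinge loss.
#' * `ksvm` — the same margin model on a randomized trigonometric feature map
#'   approximating a Gaussian kernel.
#' * `lr` — multinomial logistic regression (softmax cross-entropy).
#' * `knn` — k-nearest-neighbour voting; partially labeled neighbours spread
#'   a unit vote uniformly over their candidate set. The hierarchical variant
#'   predicts the label minimising the expected tree distance to the
#'   neighbours' votes (a tree-median vote).
#' * `rf` / `xgbm` — random forest and gradient-boosted trees behind the
#'   score contract (per-class probability as score); trainable only by full
#'   retraining, never by gradient refinement.
#'
#' The `hierarchical` flag replaces the unit margin by the tree dissimilarity
#' `C[y, y']` (margin rescaling) for `pb_*` and `svm`/`ksvm`, and switches
#' `knn` to the tree-median vote. It is not defined for `lr`, `rf`, `xgbm`.
#'
#' @param family one of `"pb_l"`, `"pb_nn"`, `"svm"`, `"ksvm"`, `"lr"`,
#'   `"knn"`, `"rf"`, `"xgbm"`
#' @param labels character vector fixing the label order (use the
#'   hierarchy's depth-first order for reproducible matrices)
#' @param hierarchical use tree-distance margin rescaling / tree-median vote
#' @param C label dissimilarity matrix from [pairwise_distances()]; required
#'   when `hierarchical = TRUE`
#' @param ... family hyperparameters: `embed_dim` (pb, default 64),
#'   `hidden` (pb_nn, default `c(128, 128)`), `n_features` and `gamma`
#'   (ksvm, default 1024 and `1/d`), `k_nn` (knn, default 15), `ntree`,
#'   `maxnodes` (rf), `nrounds`, `max_depth`, `eta` (xgbm)
#' @return an object of class `c(family, "pll_scorer")`
#' @export
pll_model <- function(family = c("pb_l", "pb_nn", "svm", "ksvm", "lr",
                                 "knn", "rf", "xgbm"),
                      labels, hierarchical = FALSE, C = NULL, ...) {
  family <- match.arg(family)
  if (hierarchical && family %in% c("lr", "rf", "xgbm"))
    stop("no hierarchical variant is defined for family '", family, "'")
  if (hierarchical && is.null(C))
    stop("hierarchical models need the dissimilarity matrix C")
  if (!is.null(C)) C <- C[labels, labels, drop = FALSE]
  hyper <- utils::modifyList(default_hyper(family), list(...))
  structure(
    list(family = family, labels = labels, hierarchical = hierarchical,
         C = C, hyper = hyper, params = NULL, store = NULL, fitobj = NULL,
         rff = NULL,
         trainable_by_gradient =
           family %in% c("pb_l", "pb_nn", "svm", "ksvm", "lr")),
    class = c(family, "pll_scorer"))
}

default_hyper <- function(family) {
  switch(family,
    pb_l  = list(embed_dim = 64L),
    pb_nn = list(embed_dim = 64L, hidden = c(128L, 128L)),
    svm   = list(),
    ksvm  = list(n_features = 1024L, gamma = NULL),
    lr    = list(),
    knn   = list(k_nn = 15L),
    rf    = list(ntree = 100L, maxnodes = NULL),
    xgbm  = list(nrounds = 50L, max_depth = 3L, eta = 0.3))
}

#' @export
print.pll_scorer <- function(x, ...) {
  cat(sprintf("<pll_scorer:%s%s> %d labels, %s\n", x$family,
              if (x$hierarchical) " (hierarchical)" else "",
              length(x$labels),
              if (is.null(x$params) && is.null(x$store) && is.null(x$fitobj))
                "untrained" else "trained"))
  invisible(x)
}

# margin matrix Delta: tree distances if hierarchical, else unit off-diagonal
delta_matrix <- function(model) {
  c_ <- length(model$labels)
  if (model$hierarchical) model$C
  else matrix(1, c_, c_) - diag(c_)
}

label_index <- function(model, y) {
  i <- match(y, model$labels)
  if (anyNA(i)) stop("unknown label(s): ", paste(unique(y[is.na(i)]), collapse = ", "))
  i
}

## ---- scoring ---------------------------------------------------------------

#' Score matrix of a model on a set of samples
#'
#' @param model a trained `pll_scorer`
#' @param X feature matrix (rows = samples)
#' @return numeric matrix samples x labels; prediction is the row argmax
#' @export
score_matrix <- function(model, X) UseMethod("score_matrix")

#' @export
score_matrix.svm <- function(model, X) {
  sweep(X %*% model$params$W, 2, model$params$b, `+`)
}

#' @export
score_matrix.lr <- function(model, X) {
  sweep(X %*% model$params$W, 2, model$params$b, `+`)
}

#' @export
score_matrix.ksvm <- function(model, X) {
  sweep(rff_map(model, X) %*% model$params$W, 2, model$params$b, `+`)
}

rff_map <- function(model, X) {
  r <- model$rff
  sqrt(2 / ncol(r$Omega)) * cos(sweep(X %*% r$Omega, 2, r$phase, `+`))
}

prototype_scores <- function(Z, P) {
  2 * tcrossprod(Z, P) - rowSums(Z^2) -
    matrix(rowSums(P^2), nrow(Z), nrow(P), byrow = TRUE)
}

#' @export
score_matrix.pb_l <- function(model, X) {
  prototype_scores(X %*% model$params$proj, model$params$P)
}

#' @export
score_matrix.pb_nn <- function(model, X) {
  prototype_scores(pb_nn_forward(model$params, X)$Z, model$params$P)
}

pb_nn_forward <- function(pr, X) {
  H1 <- tanh(sweep(X %*% pr$W1, 2, pr$b1, `+`))
  H2 <- tanh(sweep(H1 %*% pr$W2, 2, pr$b2, `+`))
  list(H1 = H1, H2 = H2, Z = sweep(H2 %*% pr$W3, 2, pr$b3, `+`))
}

#' @export
score_matrix.knn <- function(model, X) {
  st <- model$store
  if (is.null(st)) stop("kNN model has no stored training set")
  d2 <- outer(rowSums(X^2), rowSums(st$X^2), `+`) - 2 * tcrossprod(X, st$X)
  k <- min(model$hyper$k_nn, nrow(st$X))
  S <- matrix(0, nrow(X), length(model$labels))
  for (i in seq_len(nrow(X))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- colSums(st$V[nn, , drop = FALSE])
    S[i, ] <- if (model$hierarchical) -as.vector(votes %*% model$C) else votes
  }
  S
}

#' @export
score_matrix.rf <- function(model, X) {
  pr <- stats::predict(model$fitobj, X, type = "prob")
  S <- matrix(0, nrow(X), length(model$labels),
              dimnames = list(NULL, model$labels))
  S[, colnames(pr)] <- pr
  S
}

#' @export
score_matrix.xgbm <- function(model, X) {
  p <- stats::predict(model$fitobj, xgboost::xgb.DMatrix(X))
  matrix(p, nrow(X), length(model$labels), byrow = TRUE)
}

#' Predicted labels, optionally restricted to a per-sample prior
#'
#' Without a prior this is the plain argmax over all labels; with a prior
#' (one candidate set per sample) the argmax is restricted to the candidate
#' labels. Ties always break towards the smallest label index.
#'
#' @param model a trained `pll_scorer`
#' @param X feature matrix
#' @param prior optional list of candidate-label character vectors, one per
#'   row of `X`
#' @return character vector of predicted labels
#' @export
predict_labels <- function(model, X, prior = NULL) {
  S <- score_matrix(model, X)
  if (is.null(prior)) return(model$labels[row_argmax(S)])
  if (length(prior) != nrow(X)) stop("one prior per sample required")
  idx <- lapply(prior, function(p) {
    if (!length(p)) stop("empty prior candidate set")
    sort(label_index(model, p))
  })
  model$labels[vapply(seq_len(nrow(X)),
                      function(i) idx[[i]][argmax1(S[i, idx[[i]]])], 0L)]
}

## ---- losses ----------------------------------------------------------------

# structured hinge: per-sample max over rivals of max(0, Delta + s' - s)
hinge_parts <- function(S, yidx, Delta) {
  n <- nrow(S)
  A <- S + Delta[yidx, , drop = FALSE]
  A[cbind(seq_len(n), yidx)] <- -Inf
  r <- max.col(A, ties.method = "first")
  loss <- pmax(A[cbind(seq_len(n), r)] - S[cbind(seq_len(n), yidx)], 0)
  list(loss = loss, rival = r)
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Per-sample supervised loss
#'
#' Structured hinge with the model's margin (`1` flat, `C[y, y']`
#' hierarchical) for the margin and prototype families; negative log-softmax
#' of the scores for logistic regression; `-log` of the normalised score for
#' the probability/vote scorers (monitoring only — those families are not
#' trained by gradient).
#'
#' @param model a `pll_scorer`
#' @param X feature matrix
#' @param y true labels (character, one per row)
#' @return nonnegative numeric vector, one loss per sample
#' @export
supervised_loss <- function(model, X, y) {
  yidx <- label_index(model, y)
  S <- score_matrix(model, X)
  loss_from_scores(model, S, yidx, delta_matrix(model))
}

loss_from_scores <- function(model, S, yidx, Delta) {
  n <- nrow(S)
  if (model$family %in% c("pb_l", "pb_nn", "svm", "ksvm"))
    hinge_parts(S, yidx, Delta)$loss
  else if (model$family == "lr")
    -log(softmax_rows(S)[cbind(seq_len(n), yidx)])
  else {
    P <- pmax(S, 0)
    P <- P / pmax(rowSums(P), .Machine$double.eps)
    -log(P[cbind(seq_len(n), yidx)] + 1e-12)
  }
}

#' Hierarchy-rescaled margin loss
#'
#' The structured hinge of [supervised_loss()] with the unit margin replaced
#' by the tree dissimilarity `C[y, y']`: mistakes towards distant labels are
#' penalised proportionally to their distance. With `C` having unit
#' off-diagonal entries this reduces exactly to the flat loss. Defined for
#' the prototype and margin families only.
#'
#' @inheritParams supervised_loss
#' @param C label dissimilarity matrix (rows/cols in the model's label order)
#' @return nonnegative numeric vector
#' @export
hierarchical_loss <- function(model, X, y, C) {
  if (!model$family %in% c("pb_l", "pb_nn", "svm", "ksvm"))
    stop("hierarchical loss is defined for prototype and margin families only")
  if (!all(dim(C) == length(model$labels)))
    stop("C must be |labels| x |labels|")
  yidx <- label_index(model, y)
  hinge_parts(score_matrix(model, X), yidx, C)$loss
}

## ---- initialisation & gradients -------------------------------------------

# initialise trainable parameters for input dimension d (gradient families)
init_params <- function(model, d, seed = 1L) {
  c_ <- length(model$labels)
  h <- model$hyper
  with_seed(seed, {
    model$params <- switch(model$family,
      svm = , lr = list(W = matrix(stats::rnorm(d * c_, 0, 0.01), d, c_),
                        b = numeric(c_)),
      ksvm = {
        D <- h$n_features
        gamma <- h$gamma %||% (1 / d)
        model$rff <- list(Omega = matrix(stats::rnorm(d * D, 0, sqrt(2 * gamma)), d, D),
                          phase = stats::runif(D, 0, 2 * pi))
        list(W = matrix(stats::rnorm(D * c_, 0, 0.01), D, c_), b = numeric(c_))
      },
      pb_l = list(proj = matrix(stats::rnorm(d * h$embed_dim, 0, 1 / sqrt(d)),
                                d, h$embed_dim),
                  P = matrix(stats::rnorm(c_ * h$embed_dim, 0, 0.1),
                             c_, h$embed_dim)),
      pb_nn = {
        sz <- c(d, h$hidden, h$embed_dim)
        pr <- list()
        for (l in seq_len(length(sz) - 1L)) {
          pr[[paste0("W", l)]] <- matrix(stats::rnorm(sz[l] * sz[l + 1L], 0,
                                                      sqrt(2 / sz[l])),
                                         sz[l], sz[l + 1L])
          pr[[paste0("b", l)]] <- numeric(sz[l + 1L])
        }
        pr$P <- matrix(stats::rnorm(c_ * h$embed_dim, 0, 0.1), c_, h$embed_dim)
        pr
      },
      stop("family '", model$family, "' has no gradient parameters"))
  })
  model$decay_params <- intersect(names(model$params),
                                  c("W", "W1", "W2", "W3", "proj"))
  model$adam <- NULL
  model
}

# weighted data-term loss and gradients for one batch.
# wts are per-sample weights; returns sum(wts * loss) and its gradient.
forward_backward <- function(model, X, yidx, wts) {
  Delta <- delta_matrix(model)
  fam <- model$family
  pr <- model$params
  if (fam %in% c("svm", "lr", "ksvm")) {
    Phi <- if (fam == "ksvm") rff_map(model, X) else X
    S <- sweep(Phi %*% pr$W, 2, pr$b, `+`)
    G <- grad_scores(fam, S, yidx, wts, Delta)
    loss <- sum(wts * loss_from_scores(model, S, yidx, Delta))
    return(list(loss = loss,
                grads = list(W = crossprod(Phi, G), b = colSums(G))))
  }
  if (fam == "pb_l") {
    Z <- X %*% pr$proj
    S <- prototype_scores(Z, pr$P)
    G <- grad_scores(fam, S, yidx, wts, Delta)
    loss <- sum(wts * loss_from_scores(model, S, yidx, Delta))
    dZ <- 2 * (G %*% pr$P) - 2 * Z * rowSums(G)
    dP <- 2 * (crossprod(G, Z)) - 2 * pr$P * colSums(G)
    return(list(loss = loss,
                grads = list(proj = crossprod(X, dZ), P = dP)))
  }
  if (fam == "pb_nn") {
    fw <- pb_nn_forward(pr, X)
    S <- prototype_scores(fw$Z, pr$P)
    G <- grad_scores(fam, S, yidx, wts, Delta)
    loss <- sum(wts * loss_from_scores(model, S, yidx, Delta))
    dZ <- 2 * (G %*% pr$P) - 2 * fw$Z * rowSums(G)
    dP <- 2 * (crossprod(G, fw$Z)) - 2 * pr$P * colSums(G)
    dH2 <- (dZ %*% t(pr$W3)) * (1 - fw$H2^2)
    dH1 <- (dH2 %*% t(pr$W2)) * (1 - fw$H1^2)
    return(list(loss = loss,
                grads = list(W1 = crossprod(X, dH1), b1 = colSums(dH1),
                             W2 = crossprod(fw$H1, dH2), b2 = colSums(dH2),
                             W3 = crossprod(fw$H2, dZ), b3 = colSums(dZ),
                             P = dP)))
  }
  stop("family '", fam, "' is not gradient-trainable")
}

# dLoss/dScores weighted per sample (n x c)
grad_scores <- function(fam, S, yidx, wts, Delta) {
  n <- nrow(S)
  if (fam == "lr") {
    G <- softmax_rows(S) * wts
    G[cbind(seq_len(n), yidx)] <- G[cbind(seq_len(n), yidx)] - wts
    return(G)
  }
  hp <- hinge_parts(S, yidx, Delta)
  act <- hp$loss > 0
  G <- matrix(0, n, ncol(S))
  G[cbind(which(act), hp$rival[act])] <- wts[act]
  G[cbind(which(act), yidx[act])] <- G[cbind(which(act), yidx[act])] - wts[act]
  G
}

# one Adam update from accumulated gradients (plus decoupled L2 on weights)
adam_step <- function(model, grads, lr, l2) {
  if (is.null(model$adam))
    model$adam <- list(t = 0L,
                       m = lapply(model$params, function(p) p * 0),
                       v = lapply(model$params, function(p) p * 0))
  st <- model$adam
  st$t <- st$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (l2 > 0 && nm %in% model$decay_params)
      g <- g + l2 * model$params[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- st
  model
}

# plain constant-step (sub)gradient descent
sgd_step <- function(model, grads, lr, l2) {
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (l2 > 0 && nm %in% model$decay_params)
      g <- g + l2 * model$params[[nm]]
    model$params[[nm]] <- model$params[[nm]] - lr * g
  }
  model
}

# regularisation value Omega(W) = l2/2 * sum of squared weights
omega_value <- function(model, l2) {
  if (is.null(model$params) || l2 <= 0) return(0)
  l2 / 2 * sum(vapply(model$decay_params,
                      function(nm) sum(model$params[[nm]]^2), 0))
}

## ---- full fits for non-gradient families ----------------------------------

# full supervised training used inside IFR (and for the supervised method)
fit_full <- function(model, X, y, cfg) UseMethod("fit_full")

#' @export
fit_full.knn <- function(model, X, y, cfg) {
  model$store <- list(X = X, V = vote_matrix(model, y))
  model
}

# votes: full label = 1 vote; candidate list = 1/|Y_i| per candidate
vote_matrix <- function(model, y) {
  c_ <- length(model$labels)
  if (is.list(y)) {
    V <- matrix(0, length(y), c_)
    for (i in seq_along(y)) {
      idx <- label_index(model, y[[i]])
      V[i, idx] <- 1 / length(idx)
    }
    V
  } else {
    V <- matrix(0, length(y), c_)
    V[cbind(seq_along(y), label_index(model, y))] <- 1
    V
  }
}

#' @export
fit_full.rf <- function(model, X, y, cfg) {
  f <- factor(y, levels = model$labels)
  f <- droplevels(f)   # randomForest rejects empty classes
  with_seed(cfg$seed %||% 1L,
    model$fitobj <- randomForest::randomForest(
      x = X, y = f, ntree = model$hyper$ntree,
      maxnodes = model$hyper$maxnodes))
  model
}

#' @export
fit_full.xgbm <- function(model, X, y, cfg) {
  yidx <- label_index(model, y) - 1L
  dm <- xgboost::xgb.DMatrix(X, label = yidx)
  model$fitobj <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(model$labels),
                  max_depth = model$hyper$max_depth, eta = model$hyper$eta,
                  nthread = 1, seed = cfg$seed %||% 1L),
    data = dm, nrounds = model$hyper$nrounds, verbose = 0)
  model
}

#' @export
fit_full.pll_scorer <- function(model, X, y, cfg) {
  # gradient families: initialise then run cfg$epochs training epochs
  if (!model$trainable_by_gradient)
    stop("no full-fit method for family '", model$family, "'")
  if (is.null(model$params)) model <- init_params(model, ncol(X), cfg$seed)
  yidx <- label_index(model, y)
  wts <- rep(cfg$mu / length(yidx), length(yidx))
  refit_epochs(model, X, yidx, wts, cfg, n_epochs = cfg$epochs,
               seed = derive_seed(cfg$seed, 7L))
}

# minibatch Adam epochs on a fixed labeled view
refit_epochs <- function(model, X, yidx, wts, cfg, n_epochs, seed = NULL) {
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        b <- perm[start:min(start + bs - 1L, n)]
        fb <- forward_backward(model, X[b, , drop = FALSE], yidx[b],
                               wts[b] * (n / length(b)))
        model <- if (identical(cfg$optimizer, "sgd"))
          sgd_step(model, fb$grads, cfg$learning_rate, cfg$l2)
        else adam_step(model, fb$grads, cfg$learning_rate, cfg$l2)
      }
    }
  })
  model
}
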