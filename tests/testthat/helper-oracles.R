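# Independent oracles and tiny data builders used across the suite.

# Brute-force all-pairs shortest-path edge counts by BFS over the parent map.
# Deliberately independent of the package's distance code (igraph).
bfs_distances <- function(parent) {
  labs <- names(parent)
  adj <- lapply(labs, function(v) {
    nb <- c(parent[[v]], labs[!is.na(parent) & parent == v])
    nb[!is.na(nb)]
  })
  names(adj) <- labs
  D <- matrix(NA_integer_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (s in labs) {
    dist <- stats::setNames(rep(NA_integer_, length(labs)), labs)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

# random rooted tree on n nodes: node i attaches to a uniform earlier node
random_parent_map <- function(n, seed) {
  withr::with_seed(seed, {
    labs <- sprintf("n%02d", seq_len(n))
    parent <- stats::setNames(rep(NA_character_, n), labs)
    for (i in seq_len(n)[-1]) parent[labs[i]] <- labs[sample.int(i - 1L, 1L)]
    parent
  })
}

# a scorer with fully controllable scores: linear model with W = identity,
# so score_matrix(model, X) == X (columns = labels)
mock_scorer <- function(labels) {
  m <- pll_model("svm", labels = labels)
  m <- plcell:::init_params(m, d = length(labels), seed = 1L)
  m$params$W <- diag(length(labels))
  m$params$b <- numeric(length(labels))
  m
}

# well-separated Gaussian classes on a chain hierarchy: the standard toy for
# label-recovery tests. Returns pll_train_data plus the hidden truth.
gaussian_partial_toy <- function(n_labels = 4, n_sup = 15, n_partial = 50,
                                 k = 2, sep = 8, sd = 0.5, seed = 1) {
  h <- build_topology("linear", n_labels)
  C <- pairwise_distances(h)
  pools <- build_cooccurrence_pools(h, c(1, n_labels - 1), seed = seed, C = C)
  withr::with_seed(seed, {
    centers <- cbind(sep * seq_len(n_labels), sep * (seq_len(n_labels) %% 2))
    make_x <- function(lab_idx)
      cbind(stats::rnorm(length(lab_idx), centers[lab_idx, 1], sd),
            stats::rnorm(length(lab_idx), centers[lab_idx, 2], sd))
    sup_idx <- rep(seq_len(n_labels), each = n_sup)
    pl_idx <- rep(seq_len(n_labels), each = n_partial)
    Xs <- make_x(sup_idx); ys <- h$labels[sup_idx]
    Xpl <- make_x(pl_idx); y_hidden <- h$labels[pl_idx]
    cand <- make_candidate_sets(y_hidden, pools, k = k,
                                seed = seed + 1000)
    list(h = h, C = C,
         data = pll_train_data(Xs, ys, Xpl, cand),
         y_hidden = y_hidden)
  })
}

fast_cfg <- function(...) {
  base <- list(warmup_epochs = 100L, epochs = 150L, max_iterations = 50L,
               learning_rate = 0.05, batch_size = 64L)
  do.call(train_config, utils::modifyList(base, list(...)))
}
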