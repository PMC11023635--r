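#' Scenario configuration for partial-label experiments
#'
#' Bundles the knobs that define a partially labeled experimental setting:
#' * `o` — label overlap between the supervised and partially labeled
#'   training subsets (0 = disjoint label groups, 1 = identical);
#' * `n` — supervised samples per label (simulated data) or `p` — fraction of
#'   a label's training samples that are fully supervised (real data);
#'   exactly one of the two must be given;
#' * `k` — candidate-set size for every partially labeled sample;
#' * `interval` — closed tree-distance interval `c(imin, imax)` from which
#'   candidate distractors are drawn;
#' * `pairs_per_label` — size of each label's co-occurrence pool;
#' * `partial_per_label` / `partial_fraction` — partially labeled training
#'   samples per label (simulated mode) or fraction of the remaining training
#'   samples (real mode);
#' * `test_fraction` — per-label fraction reserved for testing;
#' * `seed` — drives every random choice of the scenario.
#'
#' @param o overlap, 0 or 1
#' @param n,p supervision budget (give exactly one)
#' @param k candidate-set size (>= 1)
#' @param interval integer `c(imin, imax)`, `imin >= 1`
#' @param pairs_per_label co-occurrence pool size, default 15
#' @param partial_per_label partial samples per label (simulated mode)
#' @param partial_fraction fraction of remaining training samples made
#'   partial (real mode, used when `p` is given)
#' @param test_fraction per-label test reserve
#' @param seed integer seed
#' @return a `scenario_config` list
#' @export
scenario_config <- function(o, n = NULL, p = NULL, k, interval,
                            pairs_per_label = 15L, partial_per_label = 200L,
                            partial_fraction = 0.8, test_fraction = 0.2,
                            seed = 1L) {
  if (!(o %in% c(0, 1))) stop("o must be 0 or 1")
  if (is.null(n) == is.null(p)) stop("give exactly one of n (simulated) or p (real)")
  if (k < 1) stop("k must be >= 1")
  stopifnot(length(interval) == 2L, interval[1] >= 1, interval[2] >= interval[1])
  structure(list(o = o, n = n, p = p, k = as.integer(k),
                 interval = as.integer(interval),
                 pairs_per_label = as.integer(pairs_per_label),
                 partial_per_label = as.integer(partial_per_label),
                 partial_fraction = partial_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Co-occurrence pools of confusable labels
#'
#' For every label, draws a pool of labels it can be confounded with: up to
#' `pairs_per_label` distinct labels sampled uniformly (without replacement)
#' from the labels whose tree distance from the key lies in `interval`.
#' Candidate-set distractors are later sampled from these pools, which makes
#' label co-occurrence in the partial annotations structured rather than
#' uniform over the whole label set.
#'
#' @inheritParams labels_within
#' @param pairs_per_label pool size cap, default 15
#' @param seed integer seed
#' @return named list mapping each label to its pool (character vector)
#' @export
build_cooccurrence_pools <- function(h, interval, pairs_per_label = 15L,
                                     seed = 1L, C = NULL) {
  if (is.null(C)) C <- pairwise_distances(h)
  elig <- lapply(h$labels, function(y) labels_within(h, y, interval, C = C))
  names(elig) <- h$labels
  empty <- names(elig)[lengths(elig) == 0L]
  if (length(empty))
    stop("no labels inside interval (", interval[1], ",", interval[2],
         ") for: ", paste(empty, collapse = ", "))
  with_seed(seed, {
    lapply(elig, function(e) {
      if (length(e) <= pairs_per_label) e
      else sort(sample(e, pairs_per_label))
    })
  })
}

#' Attach candidate label sets to samples
#'
#' Each sample with true label `y` receives the candidate set
#' `Y_i = {y} union (k-1 distinct labels drawn uniformly from pool(y))`, so
#' the hidden true label is always a member.
#'
#' @param truths character vector of true labels
#' @param pools pools from [build_cooccurrence_pools()]
#' @param k candidate-set size
#' @param seed integer seed
#' @return list of character vectors, each of length `k`, sorted
#' @export
make_candidate_sets <- function(truths, pools, k, seed = 1L) {
  small <- unique(truths)[vapply(unique(truths),
                                 function(y) length(pools[[y]]), 0L) < k - 1L]
  if (length(small))
    stop("pool smaller than k-1 = ", k - 1L, " for label(s): ",
         paste(sprintf("%s (%d)", small, lengths(pools[small])), collapse = ", "))
  with_seed(seed, {
    lapply(truths, function(y) {
      pool <- pools[[y]]
      distr <- if (k == 1L) character(0)
               else if (length(pool) == k - 1L) pool
               else sample(pool, k - 1L)
      sort(c(y, distr))
    })
  })
}

#' Build a partially labeled train/test scenario from a labeled dataset
#'
#' Implements the full scenario protocol. Per label group: if `o = 0` the
#' labels are partitioned uniformly at random into a supervised group `Ys`
#' and a partial group `Ypl` of (near-)equal sizes; if `o = 1` every label
#' belongs to both. A per-label test reserve (`test_fraction`) is taken
#' first — split evenly between the supervised and partial test sets when a
#' label belongs to both groups. From each label's remaining cells, the
#' supervised training set takes `n` samples (or a `p` fraction), then the
#' partial training set takes `partial_per_label` samples (or
#' `partial_fraction` of what is left). Candidate sets of size `k`, drawn
#' from the co-occurrence pools, are attached to the partial training and
#' partial test samples; hidden true labels are retained for evaluation only.
#'
#' @param ds an `expression_dataset` (or any list with `counts`, `label`,
#'   `hierarchy`)
#' @param cfg a [scenario_config()]
#' @return a `pll_scenario`: list with index vectors `idx_s`, `idx_pl`,
#'   `idx_s_test`, `idx_pl_test` into the rows of `ds$counts`, labels `ys`,
#'   hidden labels `y_pl`, `y_pl_test`, supervised test labels `ys_test`,
#'   candidate lists `cand_pl`, `cand_pl_test`, label groups `Ys`, `Ypl`,
#'   the `pools`, `hierarchy`, distance matrix `C` and the `config`
#' @export
split_scenario <- function(ds, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  h <- ds$hierarchy
  C <- pairwise_distances(h)
  labs <- h$labels
  seed_groups  <- derive_seed(cfg$seed, 1L)
  seed_split   <- derive_seed(cfg$seed, 2L)
  seed_pools   <- derive_seed(cfg$seed, 3L)
  seed_cand    <- derive_seed(cfg$seed, 4L)

  if (cfg$o == 1) {
    Ys <- labs; Ypl <- labs
  } else {
    perm <- with_seed(seed_groups, sample(labs))
    half <- ceiling(length(labs) / 2)
    Ys <- sort(perm[seq_len(half)])
    Ypl <- sort(perm[-seq_len(half)])
  }

  idx_s <- idx_pl <- idx_s_test <- idx_pl_test <- integer(0)
  with_seed(seed_split, {
    for (y in labs) {
      cells <- which(ds$label == y)
      cells <- cells[sample.int(length(cells))]   # per-label shuffle
      n_test <- round(cfg$test_fraction * length(cells))
      test <- cells[seq_len(n_test)]
      rest <- cells[-seq_len(n_test)]
      in_s <- y %in% Ys; in_pl <- y %in% Ypl
      if (in_s && in_pl) {
        idx_s_test  <- c(idx_s_test,  test[seq_along(test) %% 2L == 1L])
        idx_pl_test <- c(idx_pl_test, test[seq_along(test) %% 2L == 0L])
      } else if (in_s) idx_s_test <- c(idx_s_test, test)
      else idx_pl_test <- c(idx_pl_test, test)
      if (in_s) {
        n_sup <- if (!is.null(cfg$n)) cfg$n else floor(cfg$p * length(rest))
        if (length(rest) < n_sup)
          stop("label ", y, ": ", length(rest), " training cells, need ",
               n_sup, " supervised")
        idx_s <- c(idx_s, rest[seq_len(n_sup)])
        rest <- rest[-seq_len(n_sup)]
      }
      if (in_pl) {
        n_par <- if (!is.null(cfg$n)) cfg$partial_per_label
                 else floor(cfg$partial_fraction * length(rest))
        if (length(rest) < n_par)
          stop("label ", y, ": ", length(rest),
               " cells left for partial labelling, need ", n_par)
        idx_pl <- c(idx_pl, rest[seq_len(n_par)])
      }
    }
  })

  pools <- build_cooccurrence_pools(h, cfg$interval,
                                    pairs_per_label = cfg$pairs_per_label,
                                    seed = seed_pools, C = C)
  y_pl <- ds$label[idx_pl]
  y_pl_test <- ds$label[idx_pl_test]
  cand_pl <- make_candidate_sets(y_pl, pools, cfg$k, seed = seed_cand)
  cand_pl_test <- make_candidate_sets(y_pl_test, pools, cfg$k,
                                      seed = derive_seed(cfg$seed, 5L))
  scn <- structure(
    list(idx_s = idx_s, ys = ds$label[idx_s],
         idx_pl = idx_pl, y_pl = y_pl, cand_pl = cand_pl,
         idx_s_test = idx_s_test, ys_test = ds$label[idx_s_test],
         idx_pl_test = idx_pl_test, y_pl_test = y_pl_test,
         cand_pl_test = cand_pl_test,
         Ys = Ys, Ypl = Ypl, pools = pools,
         hierarchy = h, C = C, config = cfg),
    class = "pll_scenario")
  stopifnot(abs(overlap_statistic(scn) - cfg$o) < 1e-12)
  scn
}

#' Realised label-overlap statistic of a scenario
#'
#' `|Ys intersect Ypl| / |Ys union Ypl|`, recomputed from the generated
#' label groups; equals the requested `o` by construction.
#' @param scn a `pll_scenario`
#' @export
overlap_statistic <- function(scn) {
  length(intersect(scn$Ys, scn$Ypl)) / length(union(scn$Ys, scn$Ypl))
}

#' @export
print.pll_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<pll_scenario> o=%g k=%d I=(%d,%d) | Ds: %d samples/",
                     "%d labels, Dpl: %d samples/%d labels, test: %d+%d\n"),
              cfg$o, cfg$k, cfg$interval[1], cfg$interval[2],
              length(x$idx_s), length(x$Ys), length(x$idx_pl), length(x$Ypl),
              length(x$idx_s_test), length(x$idx_pl_test)))
  invisible(x)
}

#' Extract preprocessed feature matrices for a scenario
#'
#' Fits the log/PCA preprocessing on the training rows (supervised plus
#' partial) and projects the test rows, returning ready-to-train matrices.
#'
#' @param ds the `expression_dataset` the scenario was built from
#' @param scn a `pll_scenario`
#' @param n_components principal components kept (default 100)
#' @param log_transform apply `log1p` first
#' @return list with `Xs`, `Xpl`, `Xs_test`, `Xpl_test` feature matrices
#' @export
scenario_features <- function(ds, scn, n_components = 100, log_transform = TRUE) {
  train_idx <- c(scn$idx_s, scn$idx_pl)
  test_idx <- c(scn$idx_s_test, scn$idx_pl_test)
  pp <- preprocess_features(ds$counts[train_idx, , drop = FALSE],
                            ds$counts[test_idx, , drop = FALSE],
                            n_components = n_components,
                            log_transform = log_transform)
  n_s <- length(scn$idx_s); n_st <- length(scn$idx_s_test)
  list(Xs  = pp$train[seq_len(n_s), , drop = FALSE],
       Xpl = pp$train[-seq_len(n_s), , drop = FALSE],
       Xs_test  = pp$test[seq_len(n_st), , drop = FALSE],
       Xpl_test = pp$test[-seq_len(n_st), , drop = FALSE])
}
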