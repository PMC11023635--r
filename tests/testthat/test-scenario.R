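test_that("co-occurrence pools respect the distance interval and pool cap", {
  h <- build_topology("linear", 30)
  C <- pairwise_distances(h)
  pools <- build_cooccurrence_pools(h, c(1, 2), pairs_per_label = 15, seed = 3)
  for (y in h$labels) {
    expect_lte(length(pools[[y]]), 4)         # at most 2 on each side
    expect_true(all(C[y, pools[[y]]] %in% 1:2))
  }
  # far interval on the asymmetric tree
  hb <- build_topology("branches", 21)
  Cb <- pairwise_distances(hb)
  pb <- build_cooccurrence_pools(hb, c(15, 253), seed = 3, C = Cb)
  for (y in sample(hb$labels, 10))
    expect_true(all(Cb[y, pb[[y]]] >= 15))
  # determinism; seed matters once the eligible set exceeds the pool cap
  expect_identical(pools, build_cooccurrence_pools(h, c(1, 2), seed = 3))
  expect_identical(pb, build_cooccurrence_pools(hb, c(15, 253), seed = 3, C = Cb))
  expect_false(identical(pb, build_cooccurrence_pools(hb, c(15, 253), seed = 4,
                                                      C = Cb)))
  # an unsatisfiable interval names the offending labels
  expect_error(build_cooccurrence_pools(h, c(29, 29)), "s2")
})

test_that("candidate sets contain the truth and sample the pool uniformly", {
  h <- build_topology("branches", 5)          # 21 labels
  pools <- build_cooccurrence_pools(h, c(1, 20), pairs_per_label = 15, seed = 5)
  y <- sample(h$labels, 300, replace = TRUE)
  cand <- make_candidate_sets(y, pools, k = 3, seed = 6)
  expect_true(all(lengths(cand) == 3))
  expect_true(all(mapply(`%in%`, y, cand)))
  C <- pairwise_distances(h)
  for (i in seq_along(y)) {
    d <- C[y[i], setdiff(cand[[i]], y[i])]
    expect_true(all(d >= 1 & d <= 20))
  }
  # k = 1 gives singletons, a pool of exactly k-1 is forced
  expect_identical(make_candidate_sets("b0", pools, k = 1, seed = 1)[[1]], "b0")
  forced <- make_candidate_sets(rep("x", 5), list(x = c("a", "q")), k = 3, seed = 2)
  expect_true(all(vapply(forced, function(s) setequal(s, c("a", "q", "x")), TRUE)))
  expect_error(make_candidate_sets("x", list(x = "a"), k = 5, seed = 1),
               "pool smaller")

  # uniformity: each of the 15 pool members appears with frequency ~ (k-1)/15
  key <- h$labels[1]
  stopifnot(length(pools[[key]]) == 15)
  cand4 <- make_candidate_sets(rep(key, 1000), pools, k = 4, seed = 9)
  counts <- table(factor(unlist(lapply(cand4, setdiff, key)),
                         levels = pools[[key]]))
  p <- 3 / 15
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(counts / 1000 - p) < 4 * se))
})

make_tiny_ds <- function(n_labels = 10, cells = 40, seed = 1) {
  h <- build_topology("linear", n_labels)
  simulate_cells(h, g = 3, alpha = 0.2, cells_per_label = cells,
                 n_genes = 12, seed = seed)
}

test_that("o = 0 splits the label set evenly and disjointly", {
  ds <- make_tiny_ds()
  cfg <- scenario_config(o = 0, n = 5, k = 2, interval = c(1, 9),
                         partial_per_label = 10, seed = 11)
  scn <- split_scenario(ds, cfg)
  expect_length(scn$Ys, 5)
  expect_length(scn$Ypl, 5)
  expect_length(intersect(scn$Ys, scn$Ypl), 0)
  expect_equal(overlap_statistic(scn), 0)
  expect_true(all(scn$ys %in% scn$Ys))
  expect_true(all(scn$y_pl %in% scn$Ypl))
})

test_that("o = 1 spans the label set in all four subsets", {
  ds <- make_tiny_ds()
  cfg <- scenario_config(o = 1, n = 5, k = 2, interval = c(1, 9),
                         partial_per_label = 10, seed = 11)
  scn <- split_scenario(ds, cfg)
  expect_equal(overlap_statistic(scn), 1)
  expect_setequal(unique(scn$ys), ds$hierarchy$labels)
  expect_setequal(unique(scn$y_pl), ds$hierarchy$labels)
  expect_setequal(unique(scn$ys_test), ds$hierarchy$labels)
  expect_setequal(unique(scn$y_pl_test), ds$hierarchy$labels)
})

test_that("scenario splits are disjoint, sized as configured, reproducible", {
  ds <- make_tiny_ds()
  cfg <- scenario_config(o = 1, n = 6, k = 2, interval = c(1, 9),
                         partial_per_label = 12, test_fraction = 0.2, seed = 5)
  scn <- split_scenario(ds, cfg)
  all_idx <- c(scn$idx_s, scn$idx_pl, scn$idx_s_test, scn$idx_pl_test)
  expect_false(anyDuplicated(all_idx) > 0)
  expect_equal(as.vector(table(scn$ys)), rep(6, 10))
  expect_equal(as.vector(table(scn$y_pl)), rep(12, 10))
  # 20% of 40 cells = 8 test cells per label, split between the two test sets
  expect_equal(length(scn$idx_s_test) + length(scn$idx_pl_test), 8 * 10)
  # candidate sets contain the hidden truth with distractors inside I
  expect_true(all(mapply(`%in%`, scn$y_pl, scn$cand_pl)))
  expect_true(all(mapply(`%in%`, scn$y_pl_test, scn$cand_pl_test)))
  scn2 <- split_scenario(ds, cfg)
  expect_identical(scn[c("idx_s", "idx_pl", "cand_pl")],
                   scn2[c("idx_s", "idx_pl", "cand_pl")])
})

test_that("fraction-based supervision (real-data mode) sizes the subsets", {
  ds <- make_tiny_ds()
  cfg <- scenario_config(o = 1, p = 0.5, k = 2, interval = c(1, 9),
                         partial_fraction = 0.5, seed = 2)
  scn <- split_scenario(ds, cfg)
  # 40 cells: 8 test, 32 train; 16 supervised; half of the rest partial
  expect_equal(as.vector(table(scn$ys)), rep(16, 10))
  expect_equal(as.vector(table(scn$y_pl)), rep(8, 10))
  expect_error(scenario_config(o = 1, n = 5, p = 0.5, k = 2, interval = c(1, 3)),
               "exactly one")
})

test_that("insufficient cells fail loudly with the label named", {
  ds <- make_tiny_ds(cells = 10)
  cfg <- scenario_config(o = 1, n = 20, k = 2, interval = c(1, 9),
                         partial_per_label = 5, seed = 1)
  expect_error(split_scenario(ds, cfg), "label s.*supervised")
})

test_that("scenario features have matching dimensions and no row leakage", {
  ds <- make_tiny_ds()
  cfg <- scenario_config(o = 1, n = 5, k = 2, interval = c(1, 9),
                         partial_per_label = 10, seed = 3)
  scn <- split_scenario(ds, cfg)
  feats <- scenario_features(ds, scn, n_components = 8)
  expect_equal(nrow(feats$Xs), length(scn$idx_s))
  expect_equal(nrow(feats$Xpl), length(scn$idx_pl))
  expect_equal(nrow(feats$Xs_test), length(scn$idx_s_test))
  expect_equal(nrow(feats$Xpl_test), length(scn$idx_pl_test))
  expect_equal(ncol(feats$Xs), 8)
})
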