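#' Simulate tree-structured single-cell count data
#'
#' Generates scRNA-seq-like counts along a differentiation trajectory given by
#' a label hierarchy. Expression is driven by `g` latent "genetic programs"
#' that evolve as random walks on the tree: each tree node carries a vector
#' of `g` program levels at the *end* of its segment, a child's end-levels
#' being its parent's plus a Gaussian step (truncated at a small positive
#' floor). A cell sits at a uniform position `u` along its label's segment
#' (pseudotime = depth + `u`) and its program levels interpolate linearly
#' between the parent's end state and its own label's, so expression drifts
#' continuously along the trajectory and cells near a segment boundary are
#' genuinely confusable with the adjacent label — the property that makes
#' lineage-resolved classification hard. Each gene loads sparsely on 1-3
#' programs; its mean expression is
#' `base_expression * sum(weights * program_levels)`. Counts are drawn from a
#' negative binomial with mean `m` and variance `m + alpha * m^2`, so `alpha`
#' is the overdispersion coefficient (0.1 = low noise, 0.5 = high noise).
#'
#' @param h a [label_hierarchy()]
#' @param g number of genetic programs (>= 1)
#' @param alpha negative-binomial dispersion coefficient (> 0)
#' @param cells_per_label cells simulated at every label
#' @param n_genes number of genes (>= g)
#' @param seed integer seed; identical seeds give identical datasets
#' @param step standard deviation of one random-walk step of a program level
#' @param floor lower truncation of program levels (keeps means positive)
#' @return an object of class `expression_dataset`: list with `counts`
#'   (cells x genes integer matrix), `label` (per-cell true label),
#'   `pseudotime` (per-cell distance from the root along the trajectory),
#'   `hierarchy`, and the generating `program_model`.
#' @export
simulate_cells <- function(h, g = 50, alpha = 0.1, cells_per_label = 100,
                           n_genes = 500, seed = 1L, step = 0.3, floor = 0.01) {
  stopifnot(inherits(h, "label_hierarchy"))
  if (g < 1) stop("g must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_genes < g) stop("n_genes must be >= g")
  if (cells_per_label < 1) stop("cells_per_label must be >= 1")
  with_seed(seed, {
    pm <- program_model(h, g = g, alpha = alpha, n_genes = n_genes,
                        step = step, floor = floor)
    n_lab <- length(h$labels)
    n_cells <- n_lab * cells_per_label
    label <- rep(h$labels, each = cells_per_label)
    depth <- hierarchy_depths(h)
    u <- stats::runif(n_cells)
    pseudotime <- depth[label] + u
    # per-cell program levels: linear interpolation along the segment from
    # the parent's end state to the label's own; constant at the root
    par <- h$parent[label]
    par[is.na(par)] <- label[is.na(par)]
    cell_prog <- (1 - u) * pm$program_values[par, , drop = FALSE] +
      u * pm$program_values[label, , drop = FALSE]
    M <- tcrossprod(cell_prog, pm$gene_weights)      # n_cells x n_genes
    M <- sweep(M, 2, pm$base_expression, `*`)
    counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = M, size = 1 / alpha),
                     n_cells, n_genes)
    storage.mode(counts) <- "integer"
    rownames(counts) <- sprintf("cell%06d", seq_len(n_cells))
    colnames(counts) <- sprintf("g%04d", seq_len(n_genes))
    structure(list(counts = counts, label = label,
                   pseudotime = unname(pseudotime),
                   hierarchy = h, program_model = pm),
              class = "expression_dataset")
  })
}

# Random-walk program levels on the tree plus the sparse gene->program map.
# Called inside an established RNG stream.
program_model <- function(h, g, alpha, n_genes, step = 0.3, floor = 0.01) {
  n_lab <- length(h$labels)
  prog <- matrix(0, n_lab, g, dimnames = list(h$labels, NULL))
  prog[hierarchy_root(h), ] <- 1              # every program starts at level 1
  for (v in h$labels) {                       # depth-first: parents first
    p <- h$parent[[v]]
    if (!is.na(p))
      prog[v, ] <- pmax(prog[p, ] + stats::rnorm(g, 0, step), floor)
  }
  # each gene loads on 1-3 programs with Gamma weights normalised to sum 1
  n_load <- sample.int(min(3L, g), n_genes, replace = TRUE)
  W <- matrix(0, n_genes, g)
  for (i in seq_len(n_genes)) {
    p <- sample.int(g, n_load[i])
    w <- stats::rgamma(n_load[i], shape = 2, rate = 2)
    W[i, p] <- w / sum(w)
  }
  base <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 1)
  structure(list(g = g, alpha = alpha, program_values = prog,
                 gene_weights = W, base_expression = base,
                 step = step, floor = floor),
            class = "program_model")
}

# labels x genes matrix of negative-binomial means (strictly positive)
label_means <- function(pm) {
  M <- pm$program_values %*% t(pm$gene_weights)   # n_lab x n_genes
  sweep(M, 2, pm$base_expression, `*`)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes, %d labels (%s topology)\n",
              nrow(x$counts), ncol(x$counts), length(x$hierarchy$labels),
              x$hierarchy$topology))
  invisible(x)
}

#' Log-transform and project expression onto principal components
#'
#' Standard preprocessing for the classifiers: optional `log(1 + count)`
#' transform followed by PCA. The projection is fitted on the training rows
#' only and applied unchanged to the test rows, so no information leaks from
#' the test set into the feature space.
#'
#' @param train cells x genes count (or feature) matrix used to fit the PCA
#' @param test optional matrix of held-out rows to project with the fitted map
#' @param n_components number of principal components kept
#' @param log_transform apply `log1p` before the projection
#' @return list with `train` and `test` score matrices (cells x components),
#'   plus the fitted `rotation` and `center`
#' @export
preprocess_features <- function(train, test = NULL, n_components = 100,
                                log_transform = TRUE) {
  if (n_components > min(dim(train)))
    stop("n_components exceeds min(cells, genes) = ", min(dim(train)))
  f <- if (log_transform) function(m) log1p(m) else identity
  tr <- f(train)
  pc <- stats::prcomp(tr, center = TRUE, scale. = FALSE, rank. = n_components)
  out <- list(train = pc$x[, seq_len(n_components), drop = FALSE],
              rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
              center = pc$center)
  if (!is.null(test))
    out$test <- sweep(f(test), 2, pc$center) %*% out$rotation
  out
}
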