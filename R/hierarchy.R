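#' Label hierarchies
#'
#' A `label_hierarchy` is a rooted tree over the label set of a classification
#' problem, e.g. a cell-lineage tree where every node (internal segments as
#' well as terminal fates) is a label cells can carry. The tree is the prior
#' knowledge behind hierarchy-aware classification: the dissimilarity between
#' two labels is the shortest-path edge count between them.
#'
#' @param parent named character vector mapping each label to its parent
#'   label; the root has `NA`. Names are the label identifiers.
#' @param topology one of `"linear"`, `"branches"`, `"binary"`, `"custom"`.
#' @param depth_t integer depth parameter used by the benchmark topologies,
#'   `NA` for custom trees.
#' @return an object of class `label_hierarchy` with fields `labels` (labels
#'   in depth-first order from the root), `parent`, `topology`, `depth_t`.
#' @export
label_hierarchy <- function(parent, topology = "custom", depth_t = NA_integer_) {
  if (is.null(names(parent)) || anyDuplicated(names(parent)))
    stop("labels (names of `parent`) must be unique and non-empty")
  labels <- names(parent)
  root <- labels[is.na(parent)]
  if (length(root) != 1L)
    stop("hierarchy must have exactly one root, found ", length(root))
  missing_parent <- setdiff(stats::na.omit(unname(parent)), labels)
  if (length(missing_parent))
    stop("unknown parent label(s): ", paste(missing_parent, collapse = ", "))
  # depth-first ordering from the root; also proves acyclicity/connectivity
  kids <- split(labels[!is.na(parent)], factor(parent[!is.na(parent)], levels = labels))
  ordered <- character(length(labels))
  stack <- root
  i <- 0L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    i <- i + 1L
    ordered[[i]] <- v
    ch <- kids[[v]]
    if (length(ch)) stack <- c(sort(ch), stack)
  }
  if (i != length(labels))
    stop("parent links do not form a single connected tree (cycle or orphan)")
  structure(
    list(labels = ordered, parent = parent[ordered],
         topology = topology, depth_t = as.integer(depth_t)),
    class = "label_hierarchy")
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat(sprintf("<label_hierarchy> %d labels, topology = %s%s, root = '%s'\n",
              length(x$labels), x$topology,
              if (!is.na(x$depth_t)) sprintf(" (t = %d)", x$depth_t) else "",
              hierarchy_root(x)))
  invisible(x)
}

#' @rdname label_hierarchy
#' @param h a `label_hierarchy`
#' @export
hierarchy_root <- function(h) h$labels[is.na(h$parent)]

#' Depth of every label (root = 0)
#' @param h a `label_hierarchy`
#' @return named integer vector of edge distances from the root
#' @export
hierarchy_depths <- function(h) {
  depth <- stats::setNames(integer(length(h$labels)), h$labels)
  for (v in h$labels) {                      # depth-first order: parents first
    p <- h$parent[[v]]
    if (!is.na(p)) depth[[v]] <- depth[[p]] + 1L
  }
  depth
}

#' Build one of the benchmark label-tree topologies
#'
#' Three stylised differentiation-trajectory shapes are supported, each
#' parameterised by a depth `t`:
#' * `linear` — a single chain with no division; `t` labels.
#' * `branches` — asymmetric division: at each bifurcation one branch runs on
#'   as a non-dividing chain while the other keeps dividing; the label count
#'   is `sum(0:(t+1))`.
#' * `binary` — every branch divides in two at each level, a full binary tree
#'   with `sum(2^(0:(t+1)))` labels.
#'
#' @param kind `"linear"`, `"branches"` or `"binary"`
#' @param depth_t integer depth parameter, `>= 1`
#' @return a [label_hierarchy()]
#' @examples
#' length(build_topology("binary", 1)$labels)  # 7
#' @export
build_topology <- function(kind = c("linear", "branches", "binary"), depth_t) {
  kind <- match.arg(kind)
  depth_t <- as.integer(depth_t)
  if (is.na(depth_t) || depth_t < 1L) stop("depth_t must be a positive integer")
  parent <- switch(kind,
    linear = {
      lab <- sprintf("s%d", seq_len(depth_t))
      stats::setNames(c(NA_character_, lab[-depth_t]), lab)
    },
    binary = {
      # levels 0..t+1, node named by its binary path from the root
      par <- c(r = NA_character_)
      level <- "r"
      for (d in seq_len(depth_t + 1L)) {
        nxt <- as.vector(vapply(level, function(v) paste0(v, c("0", "1")), character(2)))
        par[nxt] <- rep(level, each = 2L)
        level <- nxt
      }
      par
    },
    branches = {
      # spine node b{j} divides into a chain of length (t - j) and the next
      # spine node; total count sum(0:(t+1)) = (t+1)(t+2)/2
      par <- c(b0 = NA_character_)
      for (j in 0:(depth_t - 1L)) {
        sp <- sprintf("b%d", j)
        chain_len <- depth_t - j
        if (chain_len > 0L) {
          chain <- sprintf("b%d.c%d", j, seq_len(chain_len))
          par[chain] <- c(sp, chain[-chain_len])
        }
        nxt <- sprintf("b%d", j + 1L)
        par[nxt] <- sp
      }
      par
    })
  h <- label_hierarchy(parent, topology = kind, depth_t = depth_t)
  n_expected <- switch(kind,
    linear = depth_t,
    branches = sum(0:(depth_t + 1L)),
    binary = sum(2^(0:(depth_t + 1L))))
  stopifnot(length(h$labels) == n_expected)
  h
}

#' Label dissimilarity matrix
#'
#' Shortest-path edge counts between all label pairs of a hierarchy; this is
#' the matrix `C` used as a rescaled margin by the hierarchical classifiers
#' and as the notion of distance when drawing candidate-label distractors.
#'
#' @param h a [label_hierarchy()]
#' @return symmetric integer matrix with zero diagonal, dimnames = labels
#' @export
pairwise_distances <- function(h) {
  edges <- cbind(h$parent[!is.na(h$parent)], h$labels[!is.na(h$parent)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g, algorithm = "unweighted")
  d <- d[h$labels, h$labels, drop = FALSE]
  storage.mode(d) <- "integer"
  d
}

#' Labels inside a tree-distance interval
#'
#' Returns the labels whose tree distance from `y` lies in the closed
#' interval `I = c(imin, imax)`; `y` itself is never included.
#'
#' @param h a [label_hierarchy()]
#' @param y a label of `h`
#' @param interval integer vector `c(imin, imax)` with `imin >= 1`
#' @param C optional precomputed [pairwise_distances()] matrix
#' @return character vector of labels (depth-first order)
#' @export
labels_within <- function(h, y, interval, C = NULL) {
  if (!y %in% h$labels) stop("unknown label: ", y)
  stopifnot(length(interval) == 2L, interval[1] >= 1, interval[2] >= interval[1])
  if (is.null(C)) C <- pairwise_distances(h)
  d <- C[y, ]
  h$labels[d >= interval[1] & d <= interval[2] & h$labels != y]
}

#' Read / write a label hierarchy
#'
#' Two plain-text formats are supported: a two-column `parent<TAB>child`
#' edge list (header optional, detected by whether the first parent field
#' ever reappears as a child) and Newick with labelled internal nodes
#' (branch lengths are ignored).
#'
#' @param path file path
#' @param format `"auto"` (by extension: `.nwk`/`.newick`/`.tree` is Newick,
#'   anything else edge list), `"edgelist"` or `"newick"`
#' @return a [label_hierarchy()]
#' @export
load_hierarchy <- function(path, format = c("auto", "edgelist", "newick")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(nwk|newick|tree)$", path, ignore.case = TRUE))
      "newick" else "edgelist"
  if (format == "newick")
    return(parse_newick(paste(readLines(path, warn = FALSE), collapse = "")))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty hierarchy file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed edge list (expect two tab-separated columns): ", path)
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1, ]), c("parent", "child"))) m <- m[-1, , drop = FALSE]
  if (anyDuplicated(m[, 2]))
    stop("duplicate child label(s): ", paste(unique(m[duplicated(m[, 2]), 2]), collapse = ", "))
  root <- setdiff(m[, 1], m[, 2])
  if (length(root) != 1L) stop("edge list must imply exactly one root, found: ",
                               paste(root, collapse = ", "))
  parent <- stats::setNames(c(NA_character_, m[, 1]), c(root, m[, 2]))
  label_hierarchy(parent)
}

# Minimal recursive-descent parser for the Newick subset used here: every
# node labelled, branch lengths optional and ignored. The general phylo
# container cannot faithfully hold the unary chains of linear label trees,
# hence the dedicated parser.
parse_newick <- function(text) {
  text <- gsub("\\s", "", text)
  if (!nzchar(text) || !grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing terminating ';'")
  text <- sub(";.*$", "", text)
  pos <- 1L
  n <- nchar(text)
  edges <- list()
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  read_label <- function() {
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in% c(",", ")", "(", ":"))
      pos <<- pos + 1L
    lab <- substr(text, start, pos - 1L)
    if (peek() == ":") {               # skip a branch length
      pos <<- pos + 1L
      while (pos <= n && grepl("[0-9.eE+-]", substr(text, pos, pos)))
        pos <<- pos + 1L
    }
    lab
  }
  node <- function() {
    kids <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, node())
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
    }
    lab <- read_label()
    if (!nzchar(lab)) stop("Newick hierarchy requires every node labelled")
    for (k in kids) edges[[length(edges) + 1L]] <<- c(lab, k)
    lab
  }
  root <- node()
  if (pos <= n) stop("malformed Newick: trailing characters")
  if (!length(edges)) return(label_hierarchy(stats::setNames(NA_character_, root)))
  m <- do.call(rbind, edges)
  if (anyDuplicated(m[, 2]) || root %in% m[, 2])
    stop("duplicate labels in Newick tree")
  label_hierarchy(stats::setNames(c(NA_character_, m[, 1]), c(root, m[, 2])))
}

#' @rdname load_hierarchy
#' @param h a [label_hierarchy()] to write
#' @export
write_hierarchy <- function(h, path, format = c("edgelist", "newick")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    keep <- !is.na(h$parent)
    writeLines(c("parent\tchild",
                 paste(h$parent[keep], h$labels[keep], sep = "\t")), path)
  } else {
    kids <- split(h$labels[!is.na(h$parent)],
                  factor(h$parent[!is.na(h$parent)], levels = h$labels))
    rec <- function(v) {
      ch <- kids[[v]]
      if (!length(ch)) return(v)
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", v)
    }
    writeLines(paste0(rec(hierarchy_root(h)), ";"), path)
  }
  invisible(path)
}
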