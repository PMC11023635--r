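#' Write / read an expression dataset as plain-text files
#'
#' A dataset directory holds `matrix.mtx` (MatrixMarket, cells x genes),
#' `cells.tsv` and `genes.tsv` (identifiers), `labels.tsv`
#' (`cell_id<TAB>label`, plus a pseudotime column when available),
#' `hierarchy.tsv` (parent/child edge list) and `manifest.json`.
#'
#' @param ds an `expression_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_expression <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds$counts), file.path(dir, "cells.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "genes.tsv"))
  lab <- data.frame(cell_id = rownames(ds$counts), label = ds$label)
  if (!is.null(ds$pseudotime)) lab$pseudotime <- ds$pseudotime
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_hierarchy(ds$hierarchy, file.path(dir, "hierarchy.tsv"))
  jsonlite::write_json(
    list(cells = nrow(ds$counts), genes = ncol(ds$counts),
         labels = length(ds$hierarchy$labels),
         topology = ds$hierarchy$topology),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(counts) <- "integer"
  rownames(counts) <- readLines(file.path(dir, "cells.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  if (!identical(lab$cell_id, rownames(counts)))
    stop("cell ids in labels.tsv do not match matrix rows")
  h <- load_hierarchy(file.path(dir, "hierarchy.tsv"))
  bad <- setdiff(unique(lab$label), h$labels)
  if (length(bad)) stop("label(s) absent from hierarchy: ",
                        paste(bad, collapse = ", "))
  structure(list(counts = counts, label = lab$label,
                 pseudotime = lab$pseudotime, hierarchy = h),
            class = "expression_dataset")
}

#' Read per-cell labels or candidate sets
#'
#' `read_labels` parses `cell_id<TAB>label`; `read_candidates` parses
#' `cell_id<TAB>label1;label2;...` (semicolon-separated candidate sets).
#' Both accept an optional header line.
#'
#' @param path TSV file
#' @param hierarchy optional [label_hierarchy()] used to validate labels
#' @return `read_labels`: named character vector (names = cell ids);
#'   `read_candidates`: named list of character vectors
#' @export
read_labels <- function(path, hierarchy = NULL) {
  m <- read_two_cols(path, c("cell_id", "label"))
  out <- stats::setNames(m[, 2], m[, 1])
  validate_labels(out, hierarchy)
  out
}

#' @rdname read_labels
#' @export
read_candidates <- function(path, hierarchy = NULL) {
  m <- read_two_cols(path, c("cell_id", "labels"))
  out <- stats::setNames(strsplit(m[, 2], ";", fixed = TRUE), m[, 1])
  validate_labels(unlist(out), hierarchy)
  out
}

#' @rdname read_labels
#' @param candidates named list of candidate sets to write
#' @export
write_candidates <- function(candidates, path) {
  writeLines(c("cell_id\tlabels",
               paste(names(candidates),
                     vapply(candidates, paste, "", collapse = ";"),
                     sep = "\t")), path)
  invisible(path)
}

read_two_cols <- function(path, header_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed file (expect two tab-separated columns): ", path)
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1, ]), header_names)) m <- m[-1, , drop = FALSE]
  m
}

validate_labels <- function(labs, hierarchy) {
  if (is.null(hierarchy)) return(invisible())
  bad <- setdiff(unique(labs), hierarchy$labels)
  if (length(bad)) stop("label(s) absent from hierarchy: ",
                        paste(bad, collapse = ", "))
  invisible()
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return the configuration list, schema-checked by the cli entry points
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
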