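#' Construct a cell-by-gene count matrix with per-cell metadata
#'
#' The central container of the package: sparse integer counts with cells in
#' rows and genes in columns, a per-cell metadata table, and (after
#' [log_cpm_normalize()]) a normalized layer of the same shape. Per-cell QC
#' metrics (`n_genes`, `total_counts`, `pct_mito`) are derived from the counts
#' at construction time; mitochondrial genes are recognised by symbol prefix.
#'
#' @param counts Integer matrix or `Matrix::dgCMatrix`, cells in rows, genes in
#'   columns. Column names are the gene symbols and must be unique; row names
#'   are cell identifiers (generated when absent).
#' @param cell_meta Data frame with one row per cell. Must contain `donor_id`
#'   and `group` (values `"patient"`/`"control"`); `tissue` (`"balf"`/`"blood"`)
#'   and `cluster_label` are optional.
#' @param mito_prefix Gene-symbol prefix marking mitochondrially encoded genes.
#' @param gene_blacklist Optional gene symbols dropped before any metric is
#'   computed (e.g. the rRNA genes `MT-RNR1`/`MT-RNR2`).
#'
#' @return An object of class `count_matrix` with elements `counts`,
#'   `normalized` (`NULL` until normalization) and `cell_meta` (a tibble with
#'   `cell_id`, the supplied columns, and derived `n_genes`, `total_counts`,
#'   `pct_mito`).
#' @export
count_matrix <- function(counts, cell_meta, mito_prefix = "MT-",
                         gene_blacklist = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(colnames(counts))) {
    abort("`counts` must carry gene symbols as column names.")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  }
  if (!is.null(gene_blacklist)) {
    counts <- counts[, !(colnames(counts) %in% gene_blacklist), drop = FALSE]
  }
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup)) {
    abort(paste0("Duplicate gene symbols: ", paste(dup, collapse = ", ")))
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("Counts must be nonnegative integers.")
  }
  cell_meta <- as_tibble(cell_meta)
  if (nrow(cell_meta) != nrow(counts)) {
    abort("`cell_meta` must have one row per cell.")
  }
  for (col in c("donor_id", "group")) {
    if (!col %in% names(cell_meta)) abort(paste0("`cell_meta` lacks `", col, "`."))
  }
  bad_grp <- setdiff(unique(cell_meta$group), c("patient", "control"))
  if (length(bad_grp)) {
    abort(paste0("`group` must be patient/control; found: ",
                 paste(bad_grp, collapse = ", ")))
  }
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta <- mutate(cell_meta, cell_id = rownames(counts), .before = 1)
  }
  m <- structure(
    list(counts = counts, normalized = NULL, cell_meta = cell_meta,
         mito_prefix = mito_prefix),
    class = "count_matrix"
  )
  refresh_cell_metrics(m)
}

# Recompute n_genes / total_counts / pct_mito from the current counts.
refresh_cell_metrics <- function(m) {
  counts <- m$counts
  mito <- startsWith(colnames(counts), m$mito_prefix)
  tot <- unname(Matrix::rowSums(counts))
  mito_tot <- if (any(mito))
    unname(Matrix::rowSums(counts[, mito, drop = FALSE])) else 0
  m$cell_meta$n_genes <- unname(Matrix::rowSums(counts > 0))
  m$cell_meta$total_counts <- tot
  m$cell_meta$pct_mito <- ifelse(tot > 0, 100 * mito_tot / tot, 0)
  stopifnot(all(m$cell_meta$pct_mito >= 0 & m$cell_meta$pct_mito <= 100))
  m
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%s normalized layer)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "no" else "with"))
  cat(sprintf("  donors: %d | groups: %s\n",
              length(unique(x$cell_meta$donor_id)),
              paste(sort(unique(x$cell_meta$group)), collapse = "/")))
  invisible(x)
}

#' Gene symbols of a count matrix
#' @param m A [count_matrix()].
#' @return Character vector of gene symbols.
#' @export
gene_ids <- function(m) colnames(m$counts)

#' Read a count matrix from disk
#'
#' Two on-disk dialects are supported and yield identical objects for the
#' same data: a Matrix Market directory (`matrix.mtx` in triplet form, cells
#' in rows, plus `cells.tsv` and `genes.tsv` annotation tables), and a dense
#' CSV with cells in rows, a leading `cell_id` column, and gene symbols as
#' the remaining header fields.
#'
#' @param path Directory (for `format = "mtx_dir"`) or CSV file.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param cell_meta For `"csv"`: a data frame of per-cell metadata or a path
#'   to a TSV with a `cell_id` column. Ignored for `"mtx_dir"`, where
#'   `cells.tsv` supplies it.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx_dir", "csv"),
                              cell_meta = NULL, mito_prefix = "MT-",
                              gene_blacklist = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx_path <- file.path(path, "matrix.mtx")
    for (f in c(mtx_path, file.path(path, c("cells.tsv", "genes.tsv")))) {
      if (!file.exists(f)) abort(paste0("Missing file: ", f))
    }
    counts <- tryCatch(Matrix::readMM(mtx_path),
                       error = function(e) abort(paste0(
                         "Malformed Matrix Market file ", mtx_path, ": ",
                         conditionMessage(e))))
    meta <- readr::read_tsv(file.path(path, "cells.tsv"),
                            show_col_types = FALSE)
    genes <- readr::read_tsv(file.path(path, "genes.tsv"),
                             show_col_types = FALSE)
    if (!"gene_id" %in% names(genes)) abort("genes.tsv lacks a `gene_id` column.")
    counts <- methods::as(counts, "CsparseMatrix")
    colnames(counts) <- genes$gene_id
    rownames(counts) <- meta$cell_id
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (names(df)[1] != "cell_id") abort("CSV must start with a `cell_id` column.")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$cell_id
    if (is.character(cell_meta)) {
      cell_meta <- readr::read_tsv(cell_meta, show_col_types = FALSE)
    }
    if (is.null(cell_meta)) abort("`cell_meta` is required for CSV input.")
    meta <- as_tibble(cell_meta)
    meta <- meta[match(df$cell_id, meta$cell_id), ]
  }
  count_matrix(counts, meta, mito_prefix = mito_prefix,
               gene_blacklist = gene_blacklist)
}

#' Write a count matrix to a Matrix Market directory
#'
#' Inverse of [read_count_matrix()] for the `mtx_dir` dialect.
#'
#' @param m A [count_matrix()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  keep <- setdiff(names(m$cell_meta), c("n_genes", "total_counts", "pct_mito"))
  readr::write_tsv(m$cell_meta[, keep], file.path(path, "cells.tsv"))
  readr::write_tsv(tibble(gene_id = gene_ids(m)), file.path(path, "genes.tsv"))
  invisible(path)
}

#' Write a count matrix to dense CSV
#' @inheritParams write_count_matrix
#' @param path Output CSV file; per-cell metadata goes to a sibling
#'   `<path>.cells.tsv`.
#' @export
write_count_matrix_csv <- function(m, path) {
  df <- as.data.frame(as.matrix(m$counts))
  df <- cbind(cell_id = rownames(m$counts), df)
  readr::write_csv(as_tibble(df), path)
  keep <- setdiff(names(m$cell_meta), c("n_genes", "total_counts", "pct_mito"))
  readr::write_tsv(m$cell_meta[, keep], paste0(path, ".cells.tsv"))
  invisible(path)
}
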