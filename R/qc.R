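#' Quality-control filtering of cells and genes
#'
#' Applies the standard droplet/well QC rules in a fixed order: genes found
#' in fewer than `min_cells_per_gene` cells are removed first; then cells
#' expressing fewer than `min_genes_per_cell` genes, and cells whose
#' mitochondrial-count percentage exceeds their tissue's ceiling, are
#' removed. Count thresholds are inclusive ("at least 3 cells", "at least
#' 100 genes" are kept); the mitochondrial rule is strict (`> max` is
#' excluded). Per-cell metrics are recomputed on the filtered gene set.
#'
#' @param m A [count_matrix()].
#' @param tissue_mito_max Named numeric, percent ceilings per tissue.
#' @param min_genes_per_cell Minimum number of expressed genes per cell.
#' @param min_cells_per_gene Minimum number of cells a gene must appear in.
#' @return The filtered [count_matrix()] (any normalized layer is dropped;
#'   renormalize after filtering).
#' @export
qc_filter <- function(m, tissue_mito_max = c(blood = 5, balf = 10),
                      min_genes_per_cell = 100, min_cells_per_gene = 3) {
  stopifnot(inherits(m, "count_matrix"))
  keep_g <- Matrix::colSums(m$counts > 0) >= min_cells_per_gene
  m$counts <- m$counts[, keep_g, drop = FALSE]
  m$normalized <- NULL
  m <- refresh_cell_metrics(m)

  meta <- m$cell_meta
  keep_c <- meta$n_genes >= min_genes_per_cell
  if ("tissue" %in% names(meta)) {
    lim <- tissue_mito_max[meta$tissue]
    keep_c <- keep_c & (is.na(lim) | meta$pct_mito <= lim)
  }
  if (!any(keep_c)) abort("QC removed every cell.")
  m$counts <- m$counts[keep_c, , drop = FALSE]
  m$cell_meta <- meta[keep_c, ]
  refresh_cell_metrics(m)
}

#' Log-CPM normalization
#'
#' Library-size normalization followed by a log transform:
#' `normalized[c, g] = ln(1 + counts[c, g] / total_counts[c] * scale)`.
#' The result is invariant to rescaling any cell's counts by a positive
#' factor.
#'
#' @param m A [count_matrix()].
#' @param scale Scale factor (counts per `scale` total).
#' @return `m` with the `normalized` layer filled in.
#' @export
log_cpm_normalize <- function(m, scale = 10000) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0)) {
    abort(paste0("Cells with zero total counts: ",
                 paste(rownames(m$counts)[tot == 0], collapse = ", ")))
  }
  norm <- Matrix::Diagonal(x = scale / tot) %*% m$counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$normalized <- norm
  m
}

#' Per-donor pseudobulk profile of one cluster
#'
#' Averages the normalized expression of each donor's cells within one
#' cluster, yielding a donor-by-gene profile for donor-level statistics.
#' Donors with no cells in the cluster are absent from the profile (not
#' zero-filled).
#'
#' @param m A normalized [count_matrix()] whose `cell_meta` has
#'   `cluster_label`.
#' @param cluster Cluster label to profile.
#' @return A `pseudobulk_profile`: list with `values` (donor x gene matrix),
#'   `donor_groups` (named character) and `cluster_label`.
#' @export
pseudobulk_mean <- function(m, cluster) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$normalized)) abort("Run log_cpm_normalize() first.")
  if (!"cluster_label" %in% names(m$cell_meta)) {
    abort("`cell_meta` lacks `cluster_label`.")
  }
  in_cl <- m$cell_meta$cluster_label == cluster
  if (!any(in_cl)) abort(paste0("Unknown cluster: ", cluster))
  meta <- m$cell_meta[in_cl, ]
  norm <- m$normalized[in_cl, , drop = FALSE]
  donors <- sort(unique(meta$donor_id))
  values <- do.call(rbind, lapply(donors, function(d) {
    Matrix::colSums(norm[meta$donor_id == d, , drop = FALSE]) /
      sum(meta$donor_id == d)
  }))
  rownames(values) <- donors
  groups <- setNames(meta$group[match(donors, meta$donor_id)], donors)
  structure(list(values = values, donor_groups = groups,
                 cluster_label = cluster),
            class = "pseudobulk_profile")
}

#' @export
print.pseudobulk_profile <- function(x, ...) {
  cat(sprintf("<pseudobulk_profile> cluster '%s': %d donors x %d genes\n",
              x$cluster_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @describeIn pseudobulk_mean Tidy a pseudobulk profile into a long tibble.
#' @param x A `pseudobulk_profile`.
#' @param ... Unused.
#' @method tidy pseudobulk_profile
#' @export
tidy.pseudobulk_profile <- function(x, ...) {
  as_tibble(x$values, rownames = "donor_id") |>
    tidyr::pivot_longer(-"donor_id", names_to = "gene", values_to = "mean_expr") |>
    mutate(group = x$donor_groups[.data$donor_id],
           cluster_label = x$cluster_label)
}
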