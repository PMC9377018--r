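#' Build the triplicated training table for label consolidation
#'
#' Combines three per-cell annotations into one training table for the
#' gradient-boosting consolidator: each cell's feature vector appears three
#' times, once per annotation source, with that source's label (harmonized
#' through `label_map`) as the target. Features are the raw counts of the
#' `top_k_genes` most variable genes plus a tissue indicator, the number of
#' expressed genes, total counts, and the mitochondrial percentage.
#'
#' @param m A [count_matrix()].
#' @param labels List or data frame of three per-cell label vectors (one per
#'   annotation source), each of length `ncol = number of cells`.
#' @param label_map Named character mapping every observed source label to
#'   the common cell-type standard. Unmapped labels are an error.
#' @param top_k_genes Variance-ranked gene cap for the feature matrix
#'   (`Inf` keeps all genes).
#' @return A `training_table`: list with `features` (cell x feature sparse
#'   matrix), `rows` (tibble `cell_id`, `source`, `label`) and `cell_ids`.
#' @export
build_training_table <- function(m, labels, label_map, top_k_genes = 2000) {
  stopifnot(inherits(m, "count_matrix"))
  labels <- as.list(as.data.frame(labels, stringsAsFactors = FALSE))
  if (length(labels) != 3) abort("Exactly 3 annotation sources required.")
  n <- nrow(m$counts)
  if (!all(lengths(labels) == n)) abort("Each annotation must cover all cells.")
  observed <- unique(unlist(labels))
  unmapped <- setdiff(observed, names(label_map))
  if (length(unmapped)) {
    abort(paste0("Unmapped source labels: ", paste(unmapped, collapse = ", ")))
  }
  counts <- m$counts
  if (is.finite(top_k_genes) && ncol(counts) > top_k_genes) {
    v <- apply(as.matrix(counts), 2, stats::var)
    counts <- counts[, order(v, decreasing = TRUE)[seq_len(top_k_genes)],
                     drop = FALSE]
  }
  meta <- m$cell_meta
  tissue_blood <- if ("tissue" %in% names(meta)) {
    as.numeric(meta$tissue == "blood")
  } else rep(0, n)
  extras <- cbind(tissue_blood = tissue_blood, n_genes = meta$n_genes,
                  total_counts = meta$total_counts, pct_mito = meta$pct_mito)
  features <- methods::as(cbind(counts, Matrix::Matrix(extras, sparse = TRUE)),
                          "CsparseMatrix")
  rownames(features) <- meta$cell_id
  rows <- purrr::imap_dfr(labels, function(lab, src) {
    tibble(cell_id = meta$cell_id, source = as.character(src),
           label = unname(label_map[lab]))
  })
  structure(list(features = features, rows = rows, cell_ids = meta$cell_id),
            class = "training_table")
}

#' @export
print.training_table <- function(x, ...) {
  cat(sprintf("<training_table> %d cells x 3 sources = %d rows, %d features\n",
              length(x$cell_ids), nrow(x$rows), ncol(x$features)))
  invisible(x)
}

#' Grouped cross-validated consolidation of cell labels
#'
#' Trains a gradient-boosted decision-tree classifier on the triplicated
#' training table under `n_folds`-fold cross-validation grouped by cell:
#' all three label rows of a cell land in the same fold, so no cell is in
#' both the training and the test split of any fold. Each cell's
#' consolidated label is the class with the highest predicted probability
#' from the model that never saw it. Folds are stratified by the cell's
#' majority harmonized label where possible.
#'
#' @param t A [build_training_table()] result.
#' @param n_folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters.
#' @param subsample,colsample_bytree Row/column subsampling rates per tree;
#'   values below 1 decorrelate the trees so predictions do not hinge on a
#'   single marker gene.
#' @return A `consolidated_cells` tibble: `cell_id`, `fold`, `predicted`,
#'   and one `prob_<class>` column per class.
#' @export
grouped_cv_predict <- function(t, n_folds = 3, seed = 1, nrounds = 100,
                               max_depth = 3, eta = 0.1, subsample = 0.8,
                               colsample_bytree = 0.8) {
  stopifnot(inherits(t, "training_table"))
  cells <- t$cell_ids
  if (length(cells) < n_folds) abort("Fewer cells than folds.")
  classes <- sort(unique(t$rows$label))
  majority <- t$rows |>
    group_by(.data$cell_id) |>
    summarise(maj = names(sort(table(.data$label), decreasing = TRUE))[1],
              .groups = "drop")
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(cells))
    names(f) <- cells
    for (lab in unique(majority$maj)) {
      ids <- majority$cell_id[majority$maj == lab]
      f[ids] <- sample(rep_len(seq_len(n_folds), length(ids)))
    }
    f
  })
  row_fold <- fold_of[t$rows$cell_id]
  row_class <- match(t$rows$label, classes) - 1L
  row_feat <- t$features[t$rows$cell_id, , drop = FALSE]
  probs <- matrix(NA_real_, length(cells), length(classes),
                  dimnames = list(cells, classes))
  for (k in seq_len(n_folds)) {
    train <- row_fold != k
    missing_cls <- setdiff(classes, unique(t$rows$label[train]))
    if (length(missing_cls)) {
      warn(paste0("Fold ", k, " training data lacks class(es): ",
                  paste(missing_cls, collapse = ", ")))
    }
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    max_depth = max_depth, eta = eta,
                    subsample = subsample,
                    colsample_bytree = colsample_bytree,
                    seed = seed, nthread = 1),
      data = xgboost::xgb.DMatrix(row_feat[train, , drop = FALSE],
                                  label = row_class[train]),
      nrounds = nrounds, verbose = 0
    )
    test_cells <- cells[fold_of == k]
    p <- predict(booster,
                 xgboost::xgb.DMatrix(t$features[test_cells, , drop = FALSE]))
    if (is.null(dim(p))) p <- matrix(p, ncol = length(classes), byrow = TRUE)
    probs[test_cells, ] <- p
  }
  out <- tibble(cell_id = cells, fold = unname(fold_of),
                predicted = classes[max.col(probs, ties.method = "first")])
  prob_df <- as_tibble(probs)
  names(prob_df) <- paste0("prob_", classes)
  out <- bind_cols(out, prob_df)
  structure(out, classes = classes,
            class = c("consolidated_cells", class(out)))
}

#' Marker genes of one cluster
#'
#' Wilcoxon rank-sum test of each gene in the cluster's cells versus all
#' other cells on normalized expression (normal approximation with tie
#' correction), Bonferroni-adjusted. A gene is a marker if its adjusted
#' p-value is below `adj_p_max`, its natural-log fold change of
#' `expm1`-space means is at least `min_logfc`, and it is expressed in at
#' least `min_frac` of the cluster's cells.
#'
#' @param m A normalized [count_matrix()] with `cluster_label` metadata.
#' @param cluster Cluster to profile (needs at least 3 cells and at least 2
#'   clusters overall).
#' @param adj_p_max,min_logfc,min_frac Filter thresholds.
#' @return Tibble `gene`, `p_value`, `adj_p_value`, `log_fc`, `frac_in`,
#'   `frac_out`, sorted by adjusted p.
#' @export
marker_genes <- function(m, cluster, adj_p_max = 0.001, min_logfc = 0.4,
                         min_frac = 0.5) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$normalized)) abort("Run log_cpm_normalize() first.")
  meta <- m$cell_meta
  if (length(unique(meta$cluster_label)) < 2) abort("Need at least 2 clusters.")
  in_cl <- meta$cluster_label == cluster
  if (sum(in_cl) < 3) abort("Cluster has fewer than 3 cells.")
  x <- as.matrix(m$normalized)
  n1 <- sum(in_cl)
  n2 <- sum(!in_cl)
  rk <- matrixStats::colRanks(x, preserveShape = TRUE, ties.method = "average")
  r1 <- colSums(rk[in_cl, , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  # tie-corrected normal approximation of the rank-sum null
  tie_term <- apply(x, 2, function(v) {
    tb <- table(v)
    sum(tb^3 - tb)
  })
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (u - n1 * n2 / 2) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  mean_in <- colMeans(expm1(x[in_cl, , drop = FALSE]))
  mean_out <- colMeans(expm1(x[!in_cl, , drop = FALSE]))
  lfc <- log(mean_in + 1) - log(mean_out + 1)
  res <- tibble(
    gene = colnames(x),
    p_value = p,
    adj_p_value = pmin(p * ncol(x), 1),
    log_fc = lfc,
    frac_in = colMeans(x[in_cl, , drop = FALSE] > 0),
    frac_out = colMeans(x[!in_cl, , drop = FALSE] > 0)
  )
  res |>
    filter(.data$adj_p_value < adj_p_max, .data$log_fc >= min_logfc,
           .data$frac_in >= min_frac) |>
    arrange(.data$adj_p_value, desc(.data$log_fc))
}

#' Cluster-level annotation with marker confirmation and mixed-cell flags
#'
#' The cluster-level half of the four-step annotation: per cluster, the
#' majority consolidated cell label and its purity (majority fraction);
#' clusters below `purity_min` purity are flagged as mixed
#' ("contaminating" cells); a cluster is confirmed when at least one
#' canonical marker of its majority label (from `marker_dict`) passes
#' [marker_genes()] for that cluster. A label missing from `marker_dict`
#' leaves the cluster unconfirmed (not an error).
#'
#' @param cells A [grouped_cv_predict()] result (or any tibble with
#'   `cell_id` and `predicted`).
#' @param m A normalized [count_matrix()] with `cluster_label` metadata.
#' @param marker_dict Named list: cell-type label -> canonical marker genes.
#' @param purity_min Purity threshold below which a cluster is mixed.
#' @param ... Passed to [marker_genes()].
#' @return Tibble `cluster`, `label`, `purity`, `mixed`, `confirmed`.
#' @export
four_step_annotate <- function(cells, m, marker_dict, purity_min = 0.5, ...) {
  stopifnot(inherits(m, "count_matrix"))
  meta <- m$cell_meta
  joined <- left_join(select(meta, "cell_id", "cluster_label"),
                      select(as_tibble(cells), "cell_id", "predicted"),
                      by = "cell_id")
  purrr::map_dfr(sort(unique(joined$cluster_label)), function(cl) {
    lab <- joined$predicted[joined$cluster_label == cl]
    tab <- sort(table(lab), decreasing = TRUE)
    majority <- names(tab)[1]
    purity <- as.numeric(tab[1]) / length(lab)
    confirmed <- FALSE
    if (!is.null(marker_dict[[majority]])) {
      mk <- marker_genes(m, cl, ...)
      confirmed <- any(marker_dict[[majority]] %in% mk$gene)
    }
    tibble(cluster = cl, label = majority, purity = purity,
           mixed = purity < purity_min, confirmed = confirmed)
  })
}
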