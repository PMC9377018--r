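#' Reference signature matrix for cell-type annotation
#'
#' Reference expression used by both cluster annotators. Rows are reference
#' samples (or single per-type signature vectors), columns are genes.
#' `sample_types` maps each row to its cell type; when each cell type has
#' exactly one row (an LM22-style signature matrix), row names double as
#' cell-type names.
#'
#' @param values Numeric matrix, reference samples x genes, with unique gene
#'   column names.
#' @param sample_types Character vector (one per row) giving each sample's
#'   cell type; defaults to the row names.
#' @return A `reference_signature`.
#' @export
reference_signature <- function(values, sample_types = rownames(values)) {
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("`values` needs unique gene column names.")
  }
  if (is.null(sample_types)) abort("`sample_types` (or row names) required.")
  stopifnot(length(sample_types) == nrow(values))
  if (length(unique(sample_types)) < 2) abort("Need at least 2 cell types.")
  zero <- rowSums(abs(values)) == 0
  if (any(zero)) {
    abort(paste0("All-zero reference rows: ",
                 paste(rownames(values)[zero], collapse = ", ")))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- make.unique(sample_types)
  }
  structure(list(values = values, sample_types = sample_types),
            class = "reference_signature")
}

#' @export
print.reference_signature <- function(x, ...) {
  cat(sprintf("<reference_signature> %d samples, %d cell types, %d genes\n",
              nrow(x$values), length(unique(x$sample_types)),
              ncol(x$values)))
  invisible(x)
}

# Per-type mean signature (collapses replicate reference samples).
type_signatures <- function(ref) {
  types <- unique(ref$sample_types)
  sig <- do.call(rbind, lapply(types, function(tp) {
    colMeans(ref$values[ref$sample_types == tp, , drop = FALSE])
  }))
  rownames(sig) <- types
  sig
}

#' Fit the signature regression of one cluster (GenSigPro)
#'
#' Regresses a cluster's mean expression vector jointly on all reference
#' cell-type signature vectors (ordinary least squares with intercept,
#' i.e. a Gaussian-family GLM), over the gene symbols shared between
#' cluster and reference. Per-coefficient two-sided p-values come from the
#' standard coefficient t-test, uncorrected.
#'
#' @param cluster_mean Named numeric vector of mean expression per gene.
#' @param ref A [reference_signature()].
#' @return A `gensigpro_fit` tibble (`cell_type`, `coefficient`, `p_value`)
#'   with attributes `n_genes` and `residual_norm`.
#' @export
gensigpro_fit <- function(cluster_mean, ref) {
  stopifnot(inherits(ref, "reference_signature"))
  sig <- type_signatures(ref)
  genes <- intersect(names(cluster_mean), colnames(sig))
  if (length(genes) < nrow(sig) + 2) {
    abort("Too few shared genes for the signature regression.")
  }
  X <- Matrix::t(sig[, genes, drop = FALSE])
  X <- as.matrix(X)
  y <- cluster_mean[genes]
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1) {
    dep <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)] - 1]
    abort(paste0("Collinear reference signatures: ",
                 paste(dep, collapse = ", ")))
  }
  fit <- lm(y ~ X)
  sm <- suppressWarnings(summary(fit))$coefficients
  ct <- rownames(sig)
  out <- tibble(
    cell_type = ct,
    coefficient = unname(coef(fit)[-1]),
    p_value = unname(sm[-1, "Pr(>|t|)"])
  )
  structure(out, n_genes = length(genes),
            residual_norm = sqrt(sum(fit$residuals^2)),
            class = c("gensigpro_fit", class(out)))
}

#' Label a cluster from a signature regression fit
#'
#' The cluster receives the cell type with the largest regression
#' coefficient if that coefficient is positive and its (uncorrected)
#' p-value is below `alpha`; otherwise the cluster is `"Unassigned"`.
#' Equal top coefficients are resolved by smaller p-value, then cell-type
#' name.
#'
#' @param fit A [gensigpro_fit()] result.
#' @param alpha Uncorrected significance threshold.
#' @return Length-1 character label with attributes `coefficient` and
#'   `p_value` of the winning cell type.
#' @export
gensigpro_label <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "gensigpro_fit"))
  ord <- fit |>
    arrange(desc(.data$coefficient), .data$p_value, .data$cell_type)
  top <- ord[1, ]
  ok <- top$coefficient > 0 && is.finite(top$p_value) && top$p_value < alpha
  structure(if (ok) top$cell_type else "Unassigned",
            coefficient = top$coefficient, p_value = top$p_value)
}

# Union of pairwise "DE" genes among the remaining reference types:
# for every ordered type pair, the top-n genes by difference of per-type
# median reference expression.
reference_de_genes <- function(ref, types, n_top) {
  med <- do.call(rbind, lapply(types, function(tp) {
    matrixStats::colMedians(ref$values[ref$sample_types == tp, , drop = FALSE])
  }))
  rownames(med) <- types
  colnames(med) <- colnames(ref$values)
  genes <- character()
  for (a in types) for (b in setdiff(types, a)) {
    diff <- med[a, ] - med[b, ]
    genes <- c(genes, names(sort(diff, decreasing = TRUE))[seq_len(n_top)])
  }
  unique(genes)
}

#' Iterative correlation annotation of one cluster
#'
#' Reference-based annotation by iterative elimination: in each round, a set
#' of discriminating genes among the remaining cell types is selected from
#' the reference (union over ordered type pairs of the top genes by
#' median-signature difference), the cluster vector is Spearman-correlated
#' with every reference sample on those genes, each cell type is scored by
#' the `score_quantile` quantile of its samples' correlations (a single
#' sample scores as its own value), and the lowest-scoring type is dropped.
#' This repeats until one type survives. If the survivor's final score is
#' below `unknown_threshold` the cluster is labelled `"unknown"` — a
#' calibration obtained from randomized-reference tests.
#'
#' @param cluster_mean Named numeric vector of mean expression per gene.
#' @param ref A [reference_signature()].
#' @param unknown_threshold Minimum final correlation score.
#' @param score_quantile Quantile aggregating a type's sample correlations.
#' @param n_genes_base,decay Per-iteration gene budget per ordered type pair:
#'   `max(floor(n_genes_base * decay^iter), 5)` genes, capped by the shared
#'   gene count.
#' @return List with `label`, `score`, and `trace` (a tibble of per-iteration
#'   type scores with the dropped type flagged).
#' @export
iterative_correlation_label <- function(cluster_mean, ref,
                                        unknown_threshold = 0.1,
                                        score_quantile = 0.8,
                                        n_genes_base = 500, decay = 2 / 3) {
  stopifnot(inherits(ref, "reference_signature"))
  shared <- intersect(names(cluster_mean), colnames(ref$values))
  if (length(shared) < 2) abort("Fewer than 2 shared genes with the reference.")
  ref <- reference_signature(ref$values[, shared, drop = FALSE],
                             ref$sample_types)
  y <- cluster_mean[shared]
  types <- unique(ref$sample_types)
  trace <- list()
  it <- 0L
  final_score <- NA_real_
  while (length(types) > 1) {
    n_top <- max(floor(n_genes_base * decay^it), 5L)
    genes <- reference_de_genes(ref, types, min(n_top, length(shared)))
    if (length(genes) < 2) abort("Fewer than 2 discriminating genes left.")
    keep <- ref$sample_types %in% types
    cors <- apply(ref$values[keep, genes, drop = FALSE], 1, function(v) {
      r <- suppressWarnings(cor(y[genes], v, method = "spearman"))
      if (is.na(r)) 0 else r
    })
    smp_types <- ref$sample_types[keep]
    scores <- vapply(types, function(tp) {
      unname(quantile(cors[smp_types == tp], score_quantile, names = FALSE))
    }, numeric(1))
    drop_type <- types[order(scores, types)][1]
    trace[[length(trace) + 1]] <-
      tibble(iteration = it + 1L, cell_type = types, score = scores,
             dropped = types == drop_type)
    if (length(types) == 2) final_score <- scores[types != drop_type]
    types <- setdiff(types, drop_type)
    it <- it + 1L
  }
  label <- if (final_score < unknown_threshold) "unknown" else types
  list(label = label, score = unname(final_score),
       trace = bind_rows(trace))
}

# Mean normalized expression per cluster.
cluster_means <- function(m, cells = NULL) {
  if (is.null(m$normalized)) abort("Run log_cpm_normalize() first.")
  meta <- m$cell_meta
  idx <- cells %||% seq_len(nrow(meta))
  cls <- sort(unique(meta$cluster_label))
  out <- do.call(rbind, lapply(cls, function(cl) {
    rows <- idx[meta$cluster_label[idx] == cl]
    Matrix::colSums(m$normalized[rows, , drop = FALSE]) / length(rows)
  }))
  rownames(out) <- cls
  out
}

annotate_one <- function(mean_vec, ref, annotator, ...) {
  if (annotator == "gensigpro") {
    lab <- gensigpro_label(gensigpro_fit(mean_vec, ref), ...)
    list(label = as.character(lab), score = attr(lab, "coefficient"))
  } else {
    r <- iterative_correlation_label(mean_vec, ref, ...)
    list(label = r$label, score = r$score)
  }
}

#' Annotate clusters with bootstrap uncertainty
#'
#' Annotates every cluster of a normalized count matrix with one of the two
#' reference-based annotators, then quantifies uncertainty by resampling
#' cells with replacement within each cluster `n_boot` times, recomputing
#' the cluster means, and re-annotating. Reported per cluster: the
#' point-estimate label on the un-resampled data and the bootstrap label
#' frequencies (summing to 1).
#'
#' @param m A normalized [count_matrix()] with `cluster_label` metadata.
#' @param ref A [reference_signature()].
#' @param annotator `"gensigpro"` or `"correlation"`.
#' @param n_boot Number of bootstrap datasets.
#' @param seed Seed for the resampling.
#' @param ... Passed to the annotator.
#' @return An `annotation_result`: list with `point` (tibble `cluster`,
#'   `label`, `score`) and `freq` (tibble `cluster`, `label`, `frequency`).
#' @export
bootstrap_labels <- function(m, ref, annotator = c("gensigpro", "correlation"),
                             n_boot = 100, seed = 1, ...) {
  annotator <- match.arg(annotator)
  stopifnot(inherits(m, "count_matrix"))
  cm <- cluster_means(m)
  point <- purrr::map_dfr(rownames(cm), function(cl) {
    a <- annotate_one(cm[cl, ], ref, annotator, ...)
    tibble(cluster = cl, label = a$label, score = a$score)
  })
  meta <- m$cell_meta
  cls <- rownames(cm)
  boot_labels <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(cls, function(cl) {
        rows <- which(meta$cluster_label == cl)
        sample(rows, length(rows), replace = TRUE)
      }))
      bcm <- cluster_means(m, cells = idx)
      purrr::map_dfr(cls, function(cl) {
        tibble(boot = b, cluster = cl,
               label = annotate_one(bcm[cl, ], ref, annotator, ...)$label)
      })
    })
  })
  freq <- boot_labels |>
    count(.data$cluster, .data$label) |>
    group_by(.data$cluster) |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("cluster", "label", "frequency")
  structure(list(point = point, freq = freq, n_boot = n_boot,
                 annotator = annotator),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s, %d clusters, %d bootstraps\n",
              x$annotator, nrow(x$point), x$n_boot))
  print(x$point)
  invisible(x)
}

#' @describeIn bootstrap_labels Point labels joined with their bootstrap
#'   support.
#' @param x An `annotation_result`.
#' @param ... Unused.
#' @method tidy annotation_result
#' @export
tidy.annotation_result <- function(x, ...) {
  support <- x$freq |>
    filter(.data$label == x$point$label[match(.data$cluster,
                                              x$point$cluster)]) |>
    select("cluster", bootstrap_support = "frequency")
  left_join(x$point, support, by = "cluster") |>
    mutate(bootstrap_support = dplyr::coalesce(.data$bootstrap_support, 0))
}

#' @describeIn bootstrap_labels Stacked bar chart of bootstrap label
#'   frequencies per cluster.
#' @param object An `annotation_result`.
#' @method autoplot annotation_result
#' @export
autoplot.annotation_result <- function(object, ...) {
  ggplot(object$freq, aes(x = .data$cluster, y = .data$frequency,
                          fill = .data$label)) +
    geom_col() +
    labs(x = "cluster", y = "bootstrap frequency", fill = "label") +
    theme_minimal()
}
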