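#' Rank-biserial Wilcoxon score of two samples
#'
#' Signed, sample-size-free normalization of the Mann-Whitney U statistic:
#' `2*U/(n_x*n_y) - 1`, where `U` counts pairs with `x_i > y_j` plus half of
#' the tied pairs. Ranges over \[-1, 1\]; positive means `x` is
#' stochastically larger than `y`; 0 means stochastic equality.
#'
#' @param x,y Non-empty numeric samples.
#' @return A single number in \[-1, 1\].
#' @export
rank_biserial_score <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  2 * u / (length(x) * length(y)) - 1
}

# Shared core: per-gene rank-biserial scores for every unordered donor pair.
# `values` is cells x genes; scores are oriented s(donor_i, donor_j) with
# i < j in the (sorted) donor order, and s(b, a) = -s(a, b).
pair_scores_core <- function(values, donor, group = NULL,
                             min_expr_frac = 0.10, cluster_label = NA_character_) {
  donors <- sort(unique(donor))
  if (length(donors) < 2) abort("Need at least 2 donors with cells.")
  expr_frac <- colMeans(values > 0)
  keep <- expr_frac >= min_expr_frac
  if (!any(keep)) abort("No gene passes the expression filter.")
  values <- values[, keep, drop = FALSE]
  genes <- colnames(values)

  groups <- NULL
  if (!is.null(group)) {
    groups <- setNames(group[match(donors, donor)], donors)
    if (any(table(factor(groups, c("patient", "control"))) < 1)) {
      abort("Need at least one donor per group in the cluster.")
    }
  }
  rows_of <- lapply(donors, function(d) which(donor == d))
  names(rows_of) <- donors
  pairs <- utils::combn(length(donors), 2)
  scores <- matrix(NA_real_, length(genes), ncol(pairs),
                   dimnames = list(genes, NULL))
  for (k in seq_len(ncol(pairs))) {
    ri <- rows_of[[pairs[1, k]]]
    rj <- rows_of[[pairs[2, k]]]
    comb <- rbind(values[ri, , drop = FALSE], values[rj, , drop = FALSE])
    rk <- matrixStats::colRanks(comb, preserveShape = TRUE,
                                ties.method = "average")
    u <- colSums(rk[seq_along(ri), , drop = FALSE]) -
      length(ri) * (length(ri) + 1) / 2
    scores[, k] <- 2 * u / (length(ri) * length(rj)) - 1
  }
  structure(
    list(scores = scores,
         pairs = tibble(pair = seq_len(ncol(pairs)),
                        donor_i = donors[pairs[1, ]],
                        donor_j = donors[pairs[2, ]]),
         donors = donors,
         groups = groups,
         cell_counts = setNames(lengths(rows_of), donors),
         cluster_label = cluster_label,
         min_expr_frac = min_expr_frac),
    class = "pairwise_score_table"
  )
}

#' Per-gene pairwise donor scores within a cluster
#'
#' For every gene passing the expression filter and every unordered pair of
#' donors with cells in the cluster, computes the rank-biserial Wilcoxon
#' score of the two donors' per-cell normalized expression. Donors without
#' cells in the cluster are excluded before the gene filter; genes expressed
#' in fewer than `min_expr_frac` of the cluster's cells are disregarded.
#'
#' @param m A normalized [count_matrix()] with `cluster_label` metadata.
#' @param cluster Cluster to analyse.
#' @param min_expr_frac Minimum fraction of cells expressing a gene.
#' @return A `pairwise_score_table` holding the gene x pair score matrix
#'   (orientation `s(donor_i, donor_j)` with donors sorted; the reverse
#'   orientation is the negative), the donor list and per-donor cell counts.
#' @export
pairwise_scores <- function(m, cluster, min_expr_frac = 0.10) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$normalized)) abort("Run log_cpm_normalize() first.")
  in_cl <- m$cell_meta$cluster_label == cluster
  if (!any(in_cl)) abort(paste0("Unknown cluster: ", cluster))
  values <- as.matrix(m$normalized[in_cl, , drop = FALSE])
  meta <- m$cell_meta[in_cl, ]
  pair_scores_core(values, meta$donor_id, meta$group,
                   min_expr_frac = min_expr_frac, cluster_label = cluster)
}

#' Pairwise donor scores from a plain matrix
#'
#' Matrix-first variant of [pairwise_scores()] for data that is not wrapped
#' in a [count_matrix()] (e.g. simulated counts). Rank-based, so any
#' strictly monotone transform of `values` gives identical scores.
#'
#' @param values Cells x genes numeric matrix with gene column names.
#' @param donor Donor id per row.
#' @param group Optional group per row (`"patient"`/`"control"`).
#' @inheritParams pairwise_scores
#' @return A `pairwise_score_table`.
#' @export
pairwise_scores_matrix <- function(values, donor, group = NULL,
                                   min_expr_frac = 0) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gene", seq_len(ncol(values)))
  }
  pair_scores_core(values, donor, group, min_expr_frac = min_expr_frac)
}

#' @export
print.pairwise_score_table <- function(x, ...) {
  cat(sprintf("<pairwise_score_table> %d genes x %d donor pairs (%d donors)\n",
              nrow(x$scores), ncol(x$scores), length(x$donors)))
  invisible(x)
}

# Index/sign vectors mapping the ordered (patient, control) cross pairs of
# one assignment onto the stored unordered pair scores.
assignment_cross <- function(patients, controls, pidx) {
  ii <- rep(patients, each = length(controls))
  jj <- rep(controls, times = length(patients))
  lo <- pmin(ii, jj)
  hi <- pmax(ii, jj)
  list(idx = pidx[cbind(lo, hi)], sign = ifelse(ii < jj, 1, -1))
}

#' Median pairwise score across groups
#'
#' The donor-level test statistic: for each gene, the median of the
#' rank-biserial scores `s(patient, control)` over all ordered
#' (patient, control) donor pairs. Even pair counts use the
#' mean-of-middle-two median, so `T` lies in \[-1, 1\].
#'
#' @param t A `pairwise_score_table`.
#' @param grouping Named character mapping each donor to
#'   `"patient"`/`"control"`; defaults to the grouping stored in `t`.
#' @return Tibble with `gene` and `statistic`.
#' @export
median_cross_statistic <- function(t, grouping = NULL) {
  stopifnot(inherits(t, "pairwise_score_table"))
  grouping <- resolve_grouping(t, grouping)
  p_idx <- which(grouping[t$donors] == "patient")
  c_idx <- which(grouping[t$donors] == "control")
  pidx <- pair_index_matrix(t)
  cr <- assignment_cross(p_idx, c_idx, pidx)
  stat <- matrixStats::rowMedians(
    t$scores[, cr$idx, drop = FALSE] *
      rep(cr$sign, each = nrow(t$scores)), useNames = FALSE)
  tibble(gene = rownames(t$scores), statistic = stat)
}

resolve_grouping <- function(t, grouping) {
  if (is.null(grouping)) grouping <- t$groups
  if (is.null(grouping)) abort("No grouping available; supply `grouping`.")
  missing <- setdiff(t$donors, names(grouping))
  if (length(missing)) {
    abort(paste0("Grouping lacks donors: ", paste(missing, collapse = ", ")))
  }
  g <- grouping[t$donors]
  if (!all(c("patient", "control") %in% g)) {
    abort("Both groups must be non-empty.")
  }
  grouping
}

pair_index_matrix <- function(t) {
  nd <- length(t$donors)
  pidx <- matrix(NA_integer_, nd, nd)
  i <- match(t$pairs$donor_i, t$donors)
  j <- match(t$pairs$donor_j, t$donors)
  pidx[cbind(i, j)] <- t$pairs$pair
  pidx
}

#' Permutation test of the median pairwise score
#'
#' Evaluates the null distribution of the median pairwise Wilcoxon score by
#' reassigning donors to groups. All `choose(n_P + n_C, n_P)` assignments
#' that preserve the group sizes are enumerated when their number does not
#' exceed `max_exact`; otherwise a seeded Monte-Carlo subsample of
#' `max_exact` assignments (always including the observed one) is used. The
#' two-sided p-value is the fraction of assignments whose `|T|` is at least
#' the observed `|T|`; the observed assignment is always counted, so
#' `p >= 1/n_permutations`. Pair scores are computed once and reused — no
#' re-ranking per permutation.
#'
#' @inheritParams median_cross_statistic
#' @param max_exact Largest assignment count enumerated exhaustively.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A `de_test_result`; `tidy()` gives the per-gene table
#'   (`gene`, `statistic`, `p_value`, `direction`), `glance()` the test
#'   metadata.
#' @export
permutation_pvalue <- function(t, grouping = NULL, max_exact = 200000,
                               seed = NULL) {
  stopifnot(inherits(t, "pairwise_score_table"))
  grouping <- resolve_grouping(t, grouping)
  nd <- length(t$donors)
  if (nd < 3) abort("Need at least 3 donors for a non-trivial permutation test.")
  g <- grouping[t$donors]
  n_p <- sum(g == "patient")
  obs_p <- which(g == "patient")
  pidx <- pair_index_matrix(t)
  n_total <- choose(nd, n_p)
  exact <- n_total <= max_exact
  if (exact) {
    asg <- utils::combn(nd, n_p)
  } else {
    draw <- function() sort(sample.int(nd, n_p))
    asg <- withr::with_seed(if (is.null(seed)) 1L else seed, {
      cbind(sort(obs_p), replicate(max_exact - 1L, draw()))
    })
  }
  n_asg <- ncol(asg)
  G <- nrow(t$scores)
  tmat <- matrix(NA_real_, G, n_asg)
  all_idx <- seq_len(nd)
  for (a in seq_len(n_asg)) {
    cr <- assignment_cross(asg[, a], setdiff(all_idx, asg[, a]), pidx)
    tmat[, a] <- matrixStats::rowMedians(
      t$scores[, cr$idx, drop = FALSE] * rep(cr$sign, each = G),
      useNames = FALSE)
  }
  obs_col <- which(colSums(asg != sort(obs_p)) == 0)[1]
  t_obs <- tmat[, obs_col]
  # scores are rationals with small denominators; the tolerance only guards
  # exact ties against last-bit rounding, never separates distinct values
  p <- rowMeans(abs(tmat) >= abs(t_obs) - 1e-9)
  res <- tibble(
    gene = rownames(t$scores),
    statistic = t_obs,
    p_value = p,
    direction = dplyr::case_when(t_obs > 0 ~ "up", t_obs < 0 ~ "down",
                                 TRUE ~ "none")
  )
  structure(
    list(result = res, n_permutations = n_asg, exact = exact,
         cluster_label = t$cluster_label,
         n_patients = n_p, n_controls = nd - n_p, donors = t$donors),
    class = "de_test_result"
  )
}

#' @export
print.de_test_result <- function(x, ...) {
  cat(sprintf(
    "<de_test_result> %d genes | %d patients vs %d controls | %s%d permutations\n",
    nrow(x$result), x$n_patients, x$n_controls,
    if (x$exact) "all " else "Monte-Carlo ", x$n_permutations))
  invisible(x)
}

#' @describeIn permutation_pvalue Per-gene results as a tibble.
#' @param x A `de_test_result`.
#' @param ... Unused.
#' @method tidy de_test_result
#' @export
tidy.de_test_result <- function(x, ...) x$result

#' @describeIn permutation_pvalue One-row metadata summary.
#' @method glance de_test_result
#' @export
glance.de_test_result <- function(x, ...) {
  tibble(n_genes = nrow(x$result), n_patients = x$n_patients,
         n_controls = x$n_controls, n_permutations = x$n_permutations,
         exact = x$exact, cluster_label = x$cluster_label)
}

#' @describeIn permutation_pvalue Volcano-style plot of statistic versus
#'   -log10 p-value.
#' @param object A `de_test_result`.
#' @method autoplot de_test_result
#' @export
autoplot.de_test_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$statistic,
                           y = -log10(.data$p_value),
                           colour = .data$direction)) +
    geom_point(alpha = 0.7) +
    labs(x = "median pairwise Wilcoxon score",
         y = expression(-log[10]~p), colour = NULL) +
    theme_minimal()
}

#' Select differentially expressed genes
#'
#' Applies the bounded-statistic cutoff (inclusive, `|T| >= stat_cutoff`),
#' sorts ascending by p-value (ties broken by `|T|` descending, then gene
#' symbol), and keeps the top `top_n` genes.
#'
#' @param r A `de_test_result`.
#' @param stat_cutoff Minimum `|T|`.
#' @param top_n Maximum number of genes returned.
#' @return Tibble of selected genes with `gene`, `statistic`, `p_value`,
#'   `direction`, `rank`.
#' @export
select_de_genes <- function(r, stat_cutoff = 0.75, top_n = 300) {
  stopifnot(inherits(r, "de_test_result"))
  tidy(r) |>
    filter(abs(.data$statistic) >= stat_cutoff) |>
    arrange(.data$p_value, desc(abs(.data$statistic)), .data$gene) |>
    head(top_n) |>
    mutate(rank = dplyr::row_number())
}
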