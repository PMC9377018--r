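#' Donor-level pseudobulk profiles for gene-set distance analysis
#'
#' Prepares one [pseudobulk_mean()] profile per cluster, applying the
#' admission rules of the gene-set distance analysis: a cluster is retained
#' only if every donor has at least `min_cells_per_donor` cells in it, and
#' genes expressed in fewer than `min_expr_frac` of the cluster's cells are
#' excluded before averaging.
#'
#' @param m A normalized [count_matrix()] with `cluster_label` metadata.
#' @param min_cells_per_donor Per-donor cell minimum for cluster retention.
#' @param min_expr_frac Minimum expressed-cell fraction per gene.
#' @return Named list of `pseudobulk_profile`s (one per retained cluster).
#' @export
prepare_profiles <- function(m, min_cells_per_donor = 10,
                             min_expr_frac = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$normalized)) abort("Run log_cpm_normalize() first.")
  meta <- m$cell_meta
  donors <- unique(meta$donor_id)
  clusters <- sort(unique(meta$cluster_label))
  out <- list()
  for (cl in clusters) {
    counts_per_donor <- table(factor(meta$donor_id[meta$cluster_label == cl],
                                     levels = donors))
    if (any(counts_per_donor < min_cells_per_donor)) next
    prof <- pseudobulk_mean(m, cl)
    in_cl <- meta$cluster_label == cl
    expr_frac <- Matrix::colSums(m$normalized[in_cl, , drop = FALSE] > 0) /
      sum(in_cl)
    prof$values <- prof$values[, expr_frac >= min_expr_frac, drop = FALSE]
    out[[cl]] <- prof
  }
  if (!length(out)) abort("No cluster satisfies the per-donor cell minimum.")
  out
}

#' Gene-set distance of one set on one profile
#'
#' Restricts a donor pseudobulk profile to a gene set's members and computes
#' the group-separation ratio: the mean over all pairwise donor distances
#' divided by the sum of the mean within-patient and mean within-control
#' distances. Under exchangeability the ratio is about 0.5; values close to
#' or above 1 indicate that between-group separation dominates. Sets
#' represented by fewer than 3 genes are skipped (`NA` with a `reason`
#' attribute); a degenerate 0/0 gives `NaN` and perfect separation
#' (positive numerator, zero denominator) gives `Inf`.
#'
#' @param p A `pseudobulk_profile`.
#' @param genes Character vector of member gene symbols.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A single ratio, possibly `NA`/`NaN`/`Inf` as above, with
#'   attribute `n_genes_used`.
#' @export
gene_set_distance <- function(p, genes, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(inherits(p, "pseudobulk_profile"))
  use <- intersect(genes, colnames(p$values))
  if (length(use) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 genes present",
                     n_genes_used = length(use)))
  }
  groups <- p$donor_groups[rownames(p$values)]
  if (sum(groups == "patient") < 2 || sum(groups == "control") < 2) {
    return(structure(NA_real_, reason = "fewer than 2 donors in a group",
                     n_genes_used = length(use)))
  }
  d <- as.matrix(dist(p$values[, use, drop = FALSE], method = metric))
  pair_mean <- function(rows) {
    if (length(rows) < 2) return(NA_real_)
    mean(d[rows, rows][upper.tri(d[rows, rows])])
  }
  overall <- mean(d[upper.tri(d)])
  within_p <- pair_mean(which(groups == "patient"))
  within_c <- pair_mean(which(groups == "control"))
  denom <- within_p + within_c
  ratio <- if (denom == 0 && overall == 0) NaN
           else if (denom == 0) Inf
           else overall / denom
  structure(ratio, n_genes_used = length(use))
}

#' Rank a gene-set collection by group separation
#'
#' Computes [gene_set_distance()] for every set against one pseudobulk
#' profile and ranks defined ratios in descending order. Undefined entries
#' (too few genes, degenerate distances) are excluded from the ranking and
#' reported in the `skipped` attribute with their reason. Ties are broken
#' by `n_genes_used` (descending), then set name.
#'
#' @param collection A [gene_set_collection()].
#' @param p A `pseudobulk_profile`.
#' @param metric Distance metric, as in [gene_set_distance()].
#' @return A `gene_set_ranking` tibble (`set`, `distance`, `n_genes_used`,
#'   `rank`, `cluster_label`) with attribute `skipped`.
#' @export
rank_gene_sets <- function(collection, p,
                           metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- purrr::imap_dfr(collection$sets, function(s, nm) {
    r <- gene_set_distance(p, s$genes, metric)
    tibble(set = nm, distance = as.numeric(r),
           n_genes_used = attr(r, "n_genes_used"),
           reason = attr(r, "reason") %||%
             dplyr::case_when(is.nan(as.numeric(r)) ~ "degenerate (0/0)",
                              is.infinite(as.numeric(r)) ~
                                "perfectly separating (denominator 0)",
                              TRUE ~ NA_character_))
  })
  skipped <- rows |> filter(!is.finite(.data$distance)) |>
    select("set", "reason")
  ranked <- rows |>
    filter(is.finite(.data$distance)) |>
    arrange(desc(.data$distance), desc(.data$n_genes_used), .data$set) |>
    mutate(rank = dplyr::row_number(), cluster_label = p$cluster_label,
           metric = metric) |>
    select("set", "distance", "n_genes_used", "rank", "cluster_label",
           "metric")
  structure(ranked, skipped = skipped,
            class = c("gene_set_ranking", class(ranked)))
}

#' @describeIn rank_gene_sets Bar plot of the top-ranked gene sets.
#' @param object A `gene_set_ranking`.
#' @param top_n Number of sets to display.
#' @param ... Unused.
#' @method autoplot gene_set_ranking
#' @export
autoplot.gene_set_ranking <- function(object, top_n = 20, ...) {
  head(object, top_n) |>
    mutate(set = stats::reorder(.data$set, .data$distance)) |>
    ggplot(aes(x = .data$set, y = .data$distance)) +
    geom_col() +
    coord_flip() +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = NULL, y = "gene set distance") +
    theme_minimal()
}

#' Default stopword list for term-frequency summaries
#'
#' Filler and connective English words excluded when tokenizing gene-set
#' names.
#'
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("of", "the", "and", "or", "in", "to", "by", "via", "a", "an", "on",
    "for", "with", "from", "into", "through", "during", "involved",
    "process", "regulation", "positive", "negative", "pathway", "activity",
    "response", "cell", "cellular")
}

#' Word frequencies in top-ranked gene-set names
#'
#' Tokenizes the names of the top fraction of ranked sets on underscores and
#' whitespace, lowercases, drops collection prefixes (GO, KEGG, REACTOME,
#' HALLMARK, WP, PID, BIOCARTA) and stopwords, and counts occurrences.
#'
#' @param r A `gene_set_ranking`.
#' @param top_frac Fraction of top-ranked sets to tokenize.
#' @param stopwords Words to exclude (see [default_stopwords()]).
#' @return Tibble with `word`, `n`, sorted by decreasing count.
#' @export
term_word_frequencies <- function(r, top_frac = 0.01,
                                  stopwords = default_stopwords()) {
  stopifnot(inherits(r, "gene_set_ranking"), top_frac > 0, top_frac <= 1)
  prefixes <- c("go", "gobp", "gomf", "gocc", "kegg", "reactome", "hallmark",
                "wp", "pid", "biocarta")
  top <- head(r$set, max(1L, ceiling(top_frac * nrow(r))))
  words <- tolower(unlist(stringr::str_split(top, "[_\\s]+")))
  words <- words[nzchar(words) & !grepl("^[0-9]+$", words) &
                   !(words %in% c(prefixes, tolower(stopwords)))]
  if (!length(words)) return(tibble(word = character(), n = integer()))
  tibble(word = words) |>
    count(.data$word, sort = TRUE)
}
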