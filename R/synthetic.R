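#' Specification of one synthetic fixture
#'
#' Parameterizes the seeded generators that emulate the statistical
#' structure the methods assume: donor-structured negative-binomial counts
#' with log-normal donor means (groups differing only in dispersion for the
#' planted genes), clustered populations generated from reference cell-type
#' signatures, and gene-set collections with one planted separating set.
#' All generators are pure functions of (spec, seed): a single global seed
#' fans out to deterministic per-component child seeds.
#'
#' @param n_patients,n_controls Donors per group.
#' @param cells_per_donor Length-2 range of cells per donor.
#' @param n_genes Genes in the count fixtures.
#' @param n_clusters Clusters in the annotation fixture.
#' @param n_de_genes Planted differential genes (dispersion shift).
#' @param de_sigma Length-2 dispersion pair (patients, controls) for planted
#'   genes.
#' @param base_sigma Shared dispersion of non-planted genes.
#' @param n_cell_types Reference cell types in the annotation fixture.
#' @param markers_per_type Planted marker genes per cell type.
#' @param n_gene_sets Gene sets (1 planted + the rest null).
#' @param genes_per_set Members per null set.
#' @param mixed_cluster Add one 50/50 two-type cluster to the annotation
#'   fixture.
#' @param include_mito Prepend two mitochondrial (`MT-`) genes.
#' @param seed Global seed.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_patients = 4, n_controls = 4,
                         cells_per_donor = c(30, 60), n_genes = 200,
                         n_clusters = 3, n_de_genes = 20,
                         de_sigma = c(0.1, 0.9), base_sigma = 0.5,
                         n_cell_types = 3, markers_per_type = 15,
                         n_gene_sets = 50, genes_per_set = 10,
                         mixed_cluster = FALSE, include_mito = TRUE,
                         seed = 1) {
  stopifnot(n_de_genes <= n_genes, all(de_sigma > 0 & de_sigma < 1),
            base_sigma > 0, base_sigma < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# Deterministic child seed: global seed plus a tag-derived offset, kept
# within 32-bit integer range.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(tag)) * 131) %% 2^30)
}

#' Synthetic donor-structured grouped counts
#'
#' Generates a single-cluster [count_matrix()] whose planted genes (the
#' first `n_de_genes`, named `DEG...`) differ between patients and controls
#' only in negative-binomial dispersion (equal means through the shared
#' log-normal donor-mean law); all other genes are drawn identically for
#' both groups.
#'
#' @param spec A [fixture_spec()].
#' @return A [count_matrix()] with attribute `planted_genes`.
#' @export
synth_grouped_counts <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(child_seed(spec$seed, "grouped_counts"), {
    nd <- spec$n_patients + spec$n_controls
    groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    donors <- sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                      c(seq_len(spec$n_patients), seq_len(spec$n_controls)))
    ncell <- sample(spec$cells_per_donor[1]:spec$cells_per_donor[2], nd,
                    replace = TRUE)
    genes <- c(sprintf("DEG%03d", seq_len(spec$n_de_genes)),
               sprintf("NULLG%03d", seq_len(spec$n_genes - spec$n_de_genes)))
    if (spec$include_mito) genes <- c(genes, "MT-ND1", "MT-CO1")
    mu <- sample_donor_means(length(genes), nd)
    blocks <- vector("list", nd)
    for (d in seq_len(nd)) {
      planted_sigma <- if (groups[d] == "patient") spec$de_sigma[1] else
        spec$de_sigma[2]
      sig <- c(rep(planted_sigma, spec$n_de_genes),
               rep(spec$base_sigma, length(genes) - spec$n_de_genes))
      blocks[[d]] <- vapply(seq_along(genes), function(g) {
        simulate_counts(mu[g, d], sig[g], ncell[d])
      }, numeric(ncell[d]))
    }
    counts <- do.call(rbind, blocks)
    colnames(counts) <- genes
    meta <- tibble(
      cell_id = sprintf("cell%05d", seq_len(sum(ncell))),
      donor_id = rep(donors, ncell),
      group = rep(groups, ncell),
      tissue = "balf",
      cluster_label = "c0"
    )
    rownames(counts) <- meta$cell_id
    m <- count_matrix(counts, meta)
    attr(m, "planted_genes") <- genes[seq_len(spec$n_de_genes)]
    m
  })
}

#' Synthetic reference signatures and clustered cells
#'
#' Draws one reference signature per cell type (log-normal baseline with a
#' planted block of upregulated marker genes per type, plus replicate
#' reference samples), then generates clustered cells from the signatures
#' with negative-binomial noise. With `mixed_cluster = TRUE` the last
#' cluster draws each cell from one of two types at random.
#'
#' @param spec A [fixture_spec()].
#' @param n_ref_samples Replicate reference samples per cell type.
#' @return List with `reference` (a [reference_signature()] on the
#'   log1p scale), `matrix` (a normalized [count_matrix()] with cluster
#'   labels), and `truth` (tibble `cluster`, `cell_type`).
#' @export
synth_reference_and_clusters <- function(spec, n_ref_samples = 3) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(child_seed(spec$seed, "reference_clusters"), {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    types <- paste0("type", LETTERS[seq_len(spec$n_cell_types)])
    base <- rlnorm(spec$n_genes, 1, 0.3)
    profiles <- do.call(rbind, lapply(seq_along(types), function(i) {
      p <- base
      mk <- ((i - 1) * spec$markers_per_type + 1):(i * spec$markers_per_type)
      p[mk] <- p[mk] * 8
      p
    }))
    dimnames(profiles) <- list(types, genes)
    ref_rows <- do.call(rbind, lapply(types, function(tp) {
      t(vapply(seq_len(n_ref_samples), function(s) {
        log1p(profiles[tp, ] * rlnorm(spec$n_genes, 0, 0.05))
      }, numeric(spec$n_genes)))
    }))
    rownames(ref_rows) <- paste0(rep(types, each = n_ref_samples), "_s",
                                 rep(seq_len(n_ref_samples), length(types)))
    ref <- reference_signature(ref_rows,
                               rep(types, each = n_ref_samples))

    n_cl <- spec$n_clusters + as.integer(spec$mixed_cluster)
    cl_type <- rep_len(types, spec$n_clusters)
    nd <- spec$n_patients + spec$n_controls
    groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    donors <- sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                      c(seq_len(spec$n_patients), seq_len(spec$n_controls)))
    cells_per_cluster <- max(spec$cells_per_donor)
    all_counts <- list(); all_meta <- list(); truth <- list()
    for (k in seq_len(n_cl)) {
      mixed <- spec$mixed_cluster && k == n_cl
      n_cells <- cells_per_cluster
      pick <- if (mixed) sample(types[1:2], n_cells, replace = TRUE) else
        rep(cl_type[k], n_cells)
      cnt <- t(vapply(seq_len(n_cells), function(i) {
        mu <- profiles[pick[i], ]
        rnbinom(spec$n_genes, size = mu * 0.5 / (1 - 0.5), prob = 0.5)
      }, numeric(spec$n_genes)))
      colnames(cnt) <- genes
      all_counts[[k]] <- cnt
      all_meta[[k]] <- tibble(
        donor_id = sample(donors, n_cells, replace = TRUE),
        cluster_label = sprintf("cl%02d", k)
      )
      truth[[k]] <- tibble(cluster = sprintf("cl%02d", k),
                           cell_type = if (mixed) "mixed" else cl_type[k])
    }
    counts <- do.call(rbind, all_counts)
    meta <- bind_rows(all_meta) |>
      mutate(cell_id = sprintf("cell%05d", dplyr::row_number()),
             group = setNames(groups, donors)[.data$donor_id],
             tissue = "balf", .before = 1)
    rownames(counts) <- meta$cell_id
    m <- log_cpm_normalize(count_matrix(counts, meta))
    list(reference = ref, matrix = m, truth = bind_rows(truth))
  })
}

#' Synthetic gene-set collection with one planted separating set
#'
#' Builds a [gene_set_collection()] whose first set (`PLANTED_SEPARATING`)
#' contains exactly the planted differential genes of
#' [synth_grouped_counts()], and whose remaining sets are uniform random
#' draws from all genes (null sets of matched size).
#'
#' @param spec A [fixture_spec()].
#' @param planted_genes Planted gene symbols (attribute of
#'   [synth_grouped_counts()]).
#' @param all_genes Universe of gene symbols to draw null sets from.
#' @return A [gene_set_collection()].
#' @export
synth_gene_sets <- function(spec, planted_genes, all_genes) {
  stopifnot(inherits(spec, "fixture_spec"), length(planted_genes) >= 1)
  withr::with_seed(child_seed(spec$seed, "gene_sets"), {
    sets <- list(PLANTED_SEPARATING = list(description = "planted separating set",
                                           genes = planted_genes))
    for (i in seq_len(spec$n_gene_sets - 1)) {
      sets[[sprintf("GO_NULL_SET_%03d", i)]] <-
        list(description = "random null set",
             genes = sample(all_genes, min(spec$genes_per_set,
                                           length(all_genes))))
    }
    gene_set_collection(sets)
  })
}
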