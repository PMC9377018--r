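# In-code fixture builders shared across test files.

toy_count_matrix <- function(counts, donor, group, tissue = "balf",
                             cluster = "c0", ...) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  }
  meta <- tibble::tibble(
    cell_id = paste0("cell", seq_len(nrow(counts))),
    donor_id = donor,
    group = group,
    tissue = tissue,
    cluster_label = cluster
  )
  rownames(counts) <- meta$cell_id
  count_matrix(counts, meta, ...)
}

# One donor-structured matrix from per-donor cell value lists (single
# cluster), already "normalized" by treating the values as the normalized
# layer through raw-count identity (values must be nonnegative integers).
toy_from_cells <- function(cells, groups) {
  counts <- matrix(unlist(cells), ncol = 1,
                   dimnames = list(NULL, "g1"))
  donor <- rep(names(cells), lengths(cells))
  toy_count_matrix(counts, donor, unname(groups[donor]))
}

# Exchangeable pseudobulk profile: donors i.i.d., arbitrary labels.
random_profile <- function(n_patients = 4, n_controls = 4, n_genes = 30,
                           sd = 1) {
  donors <- c(paste0("P", seq_len(n_patients)), paste0("C", seq_len(n_controls)))
  values <- matrix(rnorm(length(donors) * n_genes, sd = sd),
                   nrow = length(donors),
                   dimnames = list(donors, paste0("g", seq_len(n_genes))))
  structure(
    list(values = values,
         donor_groups = setNames(rep(c("patient", "control"),
                                     c(n_patients, n_controls)), donors),
         cluster_label = "toy"),
    class = "pseudobulk_profile"
  )
}
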