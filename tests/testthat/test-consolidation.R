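# Shared consolidation fixture: clusters generated from reference profiles
# with known truth, three annotation sources of varying quality.
consolidation_fixture <- function(n_genes = 120, cells_per_donor = c(40, 60),
                                  seed = 71, noisy_source = TRUE) {
  spec <- fixture_spec(n_cell_types = 3, n_clusters = 3, n_genes = n_genes,
                       cells_per_donor = cells_per_donor, seed = seed)
  rc <- synth_reference_and_clusters(spec)
  truth <- rc$truth$cell_type[match(rc$matrix$cell_meta$cluster_label,
                                    rc$truth$cluster)]
  labels <- withr::with_seed(seed + 1, {
    flip <- function(x, rate) {
      idx <- runif(length(x)) < rate
      x[idx] <- sample(unique(x), sum(idx), replace = TRUE)
      x
    }
    list(src1 = paste0(truth, "_a"),
         src2 = paste0(truth, "_b"),
         src3 = paste0(if (noisy_source) flip(truth, 0.3) else truth, "_c"))
  })
  types <- paste0("type", LETTERS[1:3])
  label_map <- setNames(rep(types, 3),
                        c(paste0(types, "_a"), paste0(types, "_b"),
                          paste0(types, "_c")))
  list(m = rc$matrix, labels = labels, label_map = label_map, truth = truth)
}

test_that("training tables triplicate cells with harmonized labels", {
  fx <- consolidation_fixture()
  tt <- build_training_table(fx$m, fx$labels, fx$label_map)
  n <- nrow(fx$m$counts)
  expect_equal(nrow(tt$rows), 3 * n)
  expect_equal(unname(table(tt$rows$cell_id)), rep(3L, n),
               ignore_attr = TRUE)
  # concordant cells carry one target three times
  agree <- tt$rows |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(k = dplyr::n_distinct(label))
  concordant <- fx$labels$src1 == sub("_c$", "_a", fx$labels$src3)
  expect_true(all(agree$k[concordant[match(agree$cell_id,
                                           fx$m$cell_meta$cell_id)]] == 1))
  expect_error(
    build_training_table(fx$m, fx$labels, fx$label_map[-1]),
    "Unmapped source labels: typeA_a")
})

test_that("grouped CV never splits a cell and recovers planted labels", {
  fx <- consolidation_fixture()
  tt <- build_training_table(fx$m, fx$labels, fx$label_map)
  pred <- grouped_cv_predict(tt, seed = 4)
  # leakage check: every cell's three rows share one fold, exhaustively
  rows_fold <- dplyr::left_join(tt$rows,
                                pred[, c("cell_id", "fold")], by = "cell_id")
  per_cell <- rows_fold |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(k = dplyr::n_distinct(fold), n = dplyr::n())
  expect_true(all(per_cell$k == 1))
  expect_true(all(per_cell$n == 3))
  # probabilities are a distribution per cell
  probs <- as.matrix(pred[, grep("^prob_", names(pred))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  # 2 of 3 sources correct + separable features: planted labels recovered
  acc <- mean(pred$predicted == fx$truth)
  expect_gte(acc, 0.95)
  # fixed seed reproduces fold assignment
  pred2 <- grouped_cv_predict(tt, seed = 4)
  expect_identical(pred$fold, pred2$fold)
})

test_that("concordant sources with separable features reproduce the input", {
  fx <- consolidation_fixture(seed = 83, noisy_source = FALSE)
  tt <- build_training_table(fx$m, fx$labels, fx$label_map)
  pred <- grouped_cv_predict(tt, seed = 9)
  expect_gte(mean(pred$predicted == fx$truth), 0.99)
})

test_that("marker genes honour the quoted thresholds", {
  spec <- fixture_spec(n_cell_types = 2, n_clusters = 2, n_genes = 80,
                       markers_per_type = 10, cells_per_donor = c(60, 80),
                       seed = 29)
  rc <- synth_reference_and_clusters(spec)
  m <- rc$matrix
  mk <- marker_genes(m, "cl01")
  # planted markers of the cluster's type are strongly enriched
  planted <- sprintf("G%04d", 1:10)  # typeA marker block
  expect_gte(mean(planted %in% mk$gene), 0.9)
  # a gene below 50% in-cluster expression never passes
  low <- marker_genes(m, "cl01", min_frac = 0.5)
  expect_true(all(low$frac_in >= 0.5))
  # log-fold-change boundary is inclusive at 0.4
  all_mk <- marker_genes(m, "cl01", adj_p_max = 1.01, min_logfc = 0,
                         min_frac = 0)
  eligible <- all_mk$gene[all_mk$log_fc >= 0.4]
  strict <- marker_genes(m, "cl01", adj_p_max = 1.01, min_logfc = 0.4,
                         min_frac = 0)
  expect_setequal(strict$gene, eligible)
  expect_error(marker_genes(m, "no-such-cluster"), "fewer than 3 cells")
})

test_that("marker calls are invariant to cell order", {
  spec <- fixture_spec(n_cell_types = 2, n_clusters = 2, n_genes = 60,
                       cells_per_donor = c(30, 40), seed = 37)
  m <- synth_reference_and_clusters(spec)$matrix
  perm <- withr::with_seed(1, sample(nrow(m$counts)))
  m2 <- m
  m2$counts <- m2$counts[perm, ]
  m2$normalized <- m2$normalized[perm, ]
  m2$cell_meta <- m2$cell_meta[perm, ]
  expect_equal(marker_genes(m, "cl01")$gene, marker_genes(m2, "cl01")$gene)
})

test_that("cluster-level annotation flags purity, mixing and confirmation", {
  spec <- fixture_spec(n_cell_types = 2, n_clusters = 2, n_genes = 80,
                       markers_per_type = 10, cells_per_donor = c(60, 80),
                       mixed_cluster = TRUE, seed = 53)
  rc <- synth_reference_and_clusters(spec)
  m <- rc$matrix
  truth <- rc$truth$cell_type[match(m$cell_meta$cluster_label,
                                    rc$truth$cluster)]
  cells <- withr::with_seed(7, tibble::tibble(
    cell_id = m$cell_meta$cell_id,
    predicted = ifelse(truth == "mixed",
                       sample(c("typeA", "typeB", "typeC"), length(truth),
                              replace = TRUE),
                       truth)))
  dict <- list(typeA = sprintf("G%04d", 1:10), typeB = sprintf("G%04d", 11:20))
  ann <- four_step_annotate(cells, m, dict)
  pure <- ann[ann$cluster != "cl03", ]
  expect_true(all(!pure$mixed))
  expect_true(all(pure$purity == 1))
  expect_true(all(pure$confirmed))
  mixed <- ann[ann$cluster == "cl03", ]
  expect_true(mixed$mixed)
  expect_lt(mixed$purity, 0.65)
  # labels missing from the marker dictionary stay unconfirmed
  ann2 <- four_step_annotate(cells, m, dict[1])
  expect_false(ann2$confirmed[ann2$label == "typeB"][1])
})
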