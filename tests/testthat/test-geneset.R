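test_that("GMT files parse, deduplicate and roundtrip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst set\tTP53\tMYC\tTP53",
               "SET_B\tsecond set\tACTB\tGAPDH"), path)
  gs <- read_gmt(path)
  expect_equal(length(gs), 2)
  expect_equal(gs$sets$SET_A$genes, c("TP53", "MYC"))  # stored once
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  gs2 <- read_gmt(out)
  expect_equal(names(gs2), names(gs))
  expect_equal(tidy(gs2), tidy(gs))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tok\tTP53", "SET_B\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("profile preparation enforces the per-donor and expression rules", {
  set.seed(31)
  n <- 60
  counts <- matrix(rpois(n * 40, 5) + 1L, n, 40,
                   dimnames = list(NULL, sprintf("g%02d", 1:40)))
  # gene g40 expressed in only 4% of cells of cluster keep
  counts[, 40] <- 0L
  counts[1:2, 40] <- 3L
  donor <- rep(c("P1", "P2", "C1", "C2"), each = 15)
  group <- rep(c("patient", "patient", "control", "control"), each = 15)
  cluster <- rep("keep", n)
  cluster[56:60] <- "drop"  # C2 has only 10 cells in 'keep', 5 in 'drop'
  m <- toy_count_matrix(counts, donor, group, cluster = cluster)
  m <- log_cpm_normalize(m)
  profs <- prepare_profiles(m, min_cells_per_donor = 10,
                            min_expr_frac = 0.05)
  expect_named(profs, "keep")          # 'drop' fails the 10-cell rule
  expect_false("g40" %in% colnames(profs$keep$values))
  expect_setequal(rownames(profs$keep$values), c("P1", "P2", "C1", "C2"))
})

test_that("the 4-donor toy yields the hand-computed ratio 3.5", {
  # two constant genes + one separating gene: patients at {0, 1},
  # controls at {10, 11}; 6 pairwise distances: 1, 10, 11, 9, 10, 1
  values <- cbind(gA = c(0, 1, 10, 11), gB = 5, gC = 7)
  rownames(values) <- c("P1", "P2", "C1", "C2")
  p <- structure(list(
    values = values,
    donor_groups = c(P1 = "patient", P2 = "patient",
                     C1 = "control", C2 = "control"),
    cluster_label = "toy"), class = "pseudobulk_profile")
  r <- gene_set_distance(p, c("gA", "gB", "gC"))
  expect_equal(as.numeric(r), 3.5)
  expect_equal(attr(r, "n_genes_used"), 3)
  # identical donors -> 0/0 -> NaN; separated identical groups -> Inf
  p0 <- p; p0$values[] <- 1
  expect_true(is.nan(as.numeric(gene_set_distance(p0, c("gA", "gB", "gC")))))
  psep <- p; psep$values[, "gA"] <- c(0, 0, 10, 10)
  expect_true(is.infinite(as.numeric(gene_set_distance(psep,
                                                       c("gA", "gB", "gC")))))
  # fewer than 3 genes present: skipped with a reason
  r2 <- gene_set_distance(p, c("gA", "gB"))
  expect_true(is.na(as.numeric(r2)))
  expect_match(attr(r2, "reason"), "3 genes")
})

test_that("ratios are translation-invariant and null-centred near 0.5", {
  set.seed(55)
  p <- random_profile(n_patients = 5, n_controls = 5, n_genes = 40)
  genes <- sample(colnames(p$values), 10)
  r1 <- as.numeric(gene_set_distance(p, genes))
  p2 <- p; p2$values <- p2$values + 7
  expect_equal(as.numeric(gene_set_distance(p2, genes)), r1,
               tolerance = 1e-12)
  # orthogonal rotation of the gene space preserves Euclidean ratios
  q <- qr.Q(qr(matrix(rnorm(100), 10)))
  p3 <- p; p3$values <- p$values
  p3$values[, genes] <- p$values[, genes] %*% q
  expect_equal(as.numeric(gene_set_distance(p3, genes)), r1,
               tolerance = 1e-10)
})

test_that("a planted separating set outranks random sets", {
  spec <- fixture_spec(n_patients = 4, n_controls = 4,
                       cells_per_donor = c(40, 60), n_genes = 150,
                       n_de_genes = 15, de_sigma = c(0.1, 0.9),
                       n_gene_sets = 51, genes_per_set = 15, seed = 23)
  m <- log_cpm_normalize(synth_grouped_counts(spec))
  profs <- prepare_profiles(m, min_cells_per_donor = 10)
  gs <- synth_gene_sets(spec, attr(m, "planted_genes"), gene_ids(m))
  rk <- rank_gene_sets(gs, profs$c0)
  expect_equal(rk$set[1], "PLANTED_SEPARATING")
  # euclidean and manhattan rankings agree strongly
  rk_m <- rank_gene_sets(gs, profs$c0, metric = "manhattan")
  joined <- dplyr::inner_join(rk[, c("set", "rank")],
                              rk_m[, c("set", "rank")], by = "set")
  expect_gt(cor(joined$rank.x, joined$rank.y, method = "spearman"), 0.8)
})

test_that("ties rank adjacently in name order", {
  p <- random_profile(3, 3, 12)
  gs <- gene_set_collection(list(
    B_SET = colnames(p$values)[1:6],
    A_SET = colnames(p$values)[1:6],
    OTHER = colnames(p$values)[7:12]
  ))
  rk <- rank_gene_sets(gs, p)
  pos <- match(c("A_SET", "B_SET"), rk$set)
  expect_equal(diff(pos), 1)
  expect_lt(pos[1], pos[2])
})

test_that("the planted shift increases the ratio monotonically", {
  set.seed(101)
  base <- random_profile(4, 4, 20)
  genes <- colnames(base$values)[1:5]
  ratios <- vapply(c(0, 2, 5), function(shift) {
    p <- base
    pat <- names(base$donor_groups)[base$donor_groups == "patient"]
    p$values[pat, genes] <- p$values[pat, genes] + shift
    as.numeric(gene_set_distance(p, genes))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("word frequencies tokenize, drop prefixes and stopwords", {
  rk <- structure(
    tibble::tibble(set = c("GO_LIPID_STORAGE", "KEGG_LIPID_METABOLISM"),
                   distance = c(2, 1), n_genes_used = 5L, rank = 1:2,
                   cluster_label = "c0", metric = "euclidean"),
    class = c("gene_set_ranking", "tbl_df", "tbl", "data.frame"))
  freq <- term_word_frequencies(rk, top_frac = 1)
  expect_equal(freq$n[freq$word == "lipid"], 2)
  expect_equal(freq$n[freq$word == "storage"], 1)
  expect_equal(freq$n[freq$word == "metabolism"], 1)
  expect_false("go" %in% freq$word)
  expect_false("of" %in% freq$word)
})
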