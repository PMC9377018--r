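test_that("rank-biserial score matches enumeration and handles ties", {
  expect_equal(rank_biserial_score(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(rank_biserial_score(1:3, 1:3), 0)
  expect_equal(rank_biserial_score(c(1, 4), c(2, 3)), 0)  # U = 2 of 4 pairs
  expect_error(rank_biserial_score(numeric(0), 1), "non-empty")
  # against the independent pair-counting oracle on random draws with ties
  set.seed(42)
  for (i in 1:25) {
    x <- sample(0:5, sample(2:8, 1), replace = TRUE)
    y <- sample(0:5, sample(2:8, 1), replace = TRUE)
    expect_equal(rank_biserial_score(x, y), oracle_rank_biserial(x, y))
  }
})

test_that("pairwise score tables obey the expression filter and pair layout", {
  set.seed(7)
  # 100 cells, gene A expressed in 9% -> dropped; gene B in 12% -> kept
  n <- 100
  counts <- cbind(A = as.integer(seq_len(n) <= 9),
                  B = as.integer(seq_len(n) <= 12),
                  C = rpois(n, 5) + 1L)
  donor <- rep(paste0("d", 1:4), each = 25)
  group <- rep(c("patient", "control"), each = 50)
  tab <- pairwise_scores_matrix(counts, donor, group, min_expr_frac = 0.10)
  expect_false("A" %in% rownames(tab$scores))
  expect_true("B" %in% rownames(tab$scores))
  expect_equal(ncol(tab$scores), choose(4, 2))
  # identical constant expression across a donor pair scores 0
  const <- cbind(g = rep(3L, 20))
  tab2 <- pairwise_scores_matrix(const, rep(c("a", "b"), each = 10),
                                 rep(c("patient", "control"), each = 10))
  expect_equal(unname(tab2$scores[1, ]), 0)
})

test_that("median cross statistic matches hand-enumerated cases", {
  # 2v2 donors engineered so the four cross scores are +1, +1, -1, -1
  cells <- list(P1 = c(10, 11), P2 = c(0, 1), C1 = c(5, 6), C2 = c(5, 6))
  groups <- c(P1 = "patient", P2 = "patient", C1 = "control", C2 = "control")
  m <- toy_from_cells(cells, groups)
  m$normalized <- m$counts  # identity layer: test is rank-based
  tab <- pairwise_scores(m, "c0", min_expr_frac = 0)
  expect_equal(median_cross_statistic(tab)$statistic, 0)
  # complete separation: every patient cell above every control cell
  cells2 <- list(P1 = c(10, 11), P2 = c(8, 9), C1 = c(0, 1), C2 = c(2, 3))
  m2 <- toy_from_cells(cells2, groups)
  m2$normalized <- m2$counts
  tab2 <- pairwise_scores(m2, "c0", min_expr_frac = 0)
  expect_equal(median_cross_statistic(tab2)$statistic, 1)
  # one donor per group: statistic is the single pair score
  cells3 <- list(P1 = c(3, 9, 4), C1 = c(1, 2, 5))
  tab3 <- pairwise_scores_matrix(
    matrix(unlist(cells3), ncol = 1, dimnames = list(NULL, "g")),
    rep(c("P1", "C1"), each = 3), rep(c("patient", "control"), each = 3))
  expect_equal(median_cross_statistic(tab3)$statistic,
               oracle_rank_biserial(cells3$P1, cells3$C1))
  expect_error(median_cross_statistic(tab3, c(P1 = "patient", C1 = "patient")),
               "Both groups")
})

test_that("permutation p-values match the spec'd worked examples", {
  groups <- c(P1 = "patient", P2 = "patient", C1 = "control", C2 = "control")
  # all cells identical: T = 0 under every assignment, p = 1
  m <- toy_from_cells(list(P1 = c(2, 2), P2 = c(2, 2),
                           C1 = c(2, 2), C2 = c(2, 2)), groups)
  tab <- pairwise_scores_matrix(matrix(2, 8, 1, dimnames = list(NULL, "g")),
                                rep(names(groups), each = 2),
                                rep(unname(groups), each = 2))
  r <- permutation_pvalue(tab)
  expect_equal(tidy(r)$statistic, 0)
  expect_equal(tidy(r)$p_value, 1)
  # separated 2v2: |T| = 1 and 4 of the 6 assignments reach it
  cells <- list(P1 = c(10, 11), P2 = c(8, 9), C1 = c(0, 1), C2 = c(2, 3))
  tab2 <- pairwise_scores_matrix(
    matrix(unlist(cells), ncol = 1, dimnames = list(NULL, "g")),
    rep(names(cells), each = 2), rep(unname(groups), each = 2))
  r2 <- permutation_pvalue(tab2)
  expect_equal(abs(tidy(r2)$statistic), 1)
  expect_equal(tidy(r2)$p_value, 4 / 6)
  expect_equal(r2$n_permutations, choose(4, 2))
  # the same numbers from the independent brute-force oracle
  or <- oracle_perm_test(cells, groups)
  expect_equal(tidy(r2)$statistic, or$statistic)
  expect_equal(tidy(r2)$p_value, or$p_value)
})

test_that("9 patients + 6 controls enumerate all 5005 assignments", {
  set.seed(3)
  donors <- c(paste0("P", 1:9), paste0("C", 1:6))
  groups <- setNames(rep(c("patient", "control"), c(9, 6)), donors)
  vals <- matrix(rpois(30, 4), 30, 1, dimnames = list(NULL, "g"))
  tab <- pairwise_scores_matrix(vals, rep(donors, each = 2),
                                rep(unname(groups[donors]), each = 2))
  r <- permutation_pvalue(tab)
  expect_equal(r$n_permutations, 5005)
  expect_true(r$exact)
  expect_gte(tidy(r)$p_value, 1 / 5005)
})

test_that("label swap negates T and preserves p", {
  set.seed(9)
  cells <- lapply(1:5, function(i) rpois(6, 5))
  names(cells) <- c("P1", "P2", "P3", "C1", "C2")
  groups <- setNames(c(rep("patient", 3), rep("control", 2)), names(cells))
  flipped <- setNames(ifelse(groups == "patient", "control", "patient"),
                      names(groups))
  vals <- matrix(unlist(cells), ncol = 1, dimnames = list(NULL, "g"))
  donor <- rep(names(cells), each = 6)
  tab <- pairwise_scores_matrix(vals, donor)
  r1 <- permutation_pvalue(tab, grouping = groups)
  r2 <- permutation_pvalue(tab, grouping = flipped)
  expect_equal(tidy(r1)$statistic, -tidy(r2)$statistic)
  expect_equal(tidy(r1)$p_value, tidy(r2)$p_value)
})

test_that("the test is invariant to strictly monotone transforms", {
  set.seed(21)
  vals <- matrix(rpois(40 * 3, 6), 40, 3,
                 dimnames = list(NULL, paste0("g", 1:3)))
  donor <- rep(paste0("d", 1:5), each = 8)
  group <- rep(c("patient", "control", "patient", "control", "patient"),
               each = 8)
  r1 <- tidy(permutation_pvalue(pairwise_scores_matrix(vals, donor, group)))
  r2 <- tidy(permutation_pvalue(pairwise_scores_matrix(exp(vals / 3), donor,
                                                       group)))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("too few donors is an error", {
  tab <- pairwise_scores_matrix(matrix(1:4, 4, 1, dimnames = list(NULL, "g")),
                                rep(c("a", "b"), each = 2))
  expect_error(permutation_pvalue(tab, grouping = c(a = "patient",
                                                    b = "control")),
               "at least 3 donors")
})

test_that("DE gene selection applies cutoff, ordering and truncation", {
  res <- structure(list(result = tibble::tibble(
    gene = sprintf("g%03d", 1:400),
    statistic = c(0.74, 0.76, rep(0.9, 398)),
    p_value = c(0.01, 0.01, rep(seq(0.001, 0.05, length.out = 199), 2)),
    direction = "up"
  ), n_permutations = 100, exact = TRUE, cluster_label = "c0",
  n_patients = 2, n_controls = 2, donors = letters[1:4]),
  class = "de_test_result")
  sel <- select_de_genes(res)
  expect_false("g001" %in% sel$gene)  # |T| = 0.74 < 0.75
  expect_true("g002" %in% sel$gene)   # |T| = 0.76
  expect_equal(nrow(sel), 300)        # truncated from 399 eligible
  # p-value ties broken by |T| descending, then gene symbol
  expect_true(all(diff(sel$p_value) >= 0))
  tied <- sel[sel$p_value == sel$p_value[1], ]
  expect_true(all(diff(tied$statistic) <= 0))
})
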