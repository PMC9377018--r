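# Independent brute-force oracle for the permutation DE test. Everything is
# recomputed from raw cell values with naive pair counting; no code from the
# package's scoring path is reused.

oracle_rank_biserial <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  2 * s / (length(x) * length(y)) - 1
}

# cells: named list donor -> numeric vector of one gene's per-cell values.
# groups: named character donor -> "patient"/"control".
oracle_perm_test <- function(cells, groups) {
  donors <- names(cells)
  n_p <- sum(groups[donors] == "patient")
  asg <- combn(length(donors), n_p)
  stats <- apply(asg, 2, function(pi) {
    pats <- donors[pi]
    ctrls <- setdiff(donors, pats)
    scores <- c(outer(pats, ctrls, Vectorize(function(a, b) {
      oracle_rank_biserial(cells[[a]], cells[[b]])
    })))
    median(scores)
  })
  obs <- which(apply(asg, 2, function(pi) {
    setequal(donors[pi], donors[groups[donors] == "patient"])
  }))[1]
  list(statistic = stats[obs],
       p_value = mean(abs(stats) >= abs(stats[obs]) - 1e-9),
       n_permutations = ncol(asg))
}
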