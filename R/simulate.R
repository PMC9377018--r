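#' Parameterize one simulation benchmark cell
#'
#' One scenario of the negative-binomial benchmark: counts are drawn per
#' cell as `NB(h(mu, sigma), sigma)` with `h(mu, sigma) = mu*sigma/(1-sigma)`
#' successes and success probability `sigma`, so `E[count] = mu` for every
#' `sigma` and `Var[count] = mu/sigma`. Per-donor gene means `mu` come from
#' a shared `LogNormal(m, s)`, giving both groups identical expected
#' expression: the two groups differ only through their dispersion
#' parameters `sigma1` (patients) and `sigma2` (controls). `sigma1 == sigma2`
#' is the null ("case II"); `sigma1 != sigma2` plants a pure
#' distribution-shape difference ("case I").
#'
#' @param sigma1,sigma2 Success probabilities in (0, 1) for the patient and
#'   control group.
#' @param m,s Log-normal parameters of the donor means.
#' @param n_patients,n_controls Donors per group.
#' @param cells_per_donor Length-2 integer range; each donor's cell count is
#'   drawn uniformly from it (or a fixed vector of length
#'   `n_patients + n_controls`).
#' @param genes_per_set Genes ("mu draws") per simulated set.
#' @param n_sets Sets simulated per scenario.
#' @param seed Scenario seed; every random draw descends from it.
#' @return A `simulation_scenario`.
#' @export
simulation_scenario <- function(sigma1, sigma2, m = 1, s = 0.15,
                                n_patients = 9, n_controls = 6,
                                cells_per_donor = c(100, 500),
                                genes_per_set = 50, n_sets = 3, seed = 1) {
  stopifnot(sigma1 > 0, sigma1 < 1, sigma2 > 0, sigma2 < 1,
            genes_per_set >= 1, n_sets >= 1, s >= 0)
  structure(
    list(sigma1 = sigma1, sigma2 = sigma2, m = m, s = s,
         n_patients = n_patients, n_controls = n_controls,
         cells_per_donor = cells_per_donor, genes_per_set = genes_per_set,
         n_sets = n_sets, seed = as.integer(seed),
         case = if (sigma1 == sigma2) "II" else "I"),
    class = "simulation_scenario"
  )
}

#' Sample per-donor gene means
#'
#' Draws every donor's mean for every gene independently from the same
#' `LogNormal(m, s)` law, modelling between-individual variability that is
#' identical for both groups.
#'
#' @param n_genes,n_donors Matrix dimensions.
#' @param m,s Log-normal parameters (median `exp(m)`).
#' @param seed Optional seed.
#' @return `n_genes` x `n_donors` matrix of means.
#' @export
sample_donor_means <- function(n_genes, n_donors, m = 1, s = 0.15,
                               seed = NULL) {
  stopifnot(s >= 0)
  draw <- function() matrix(rlnorm(n_genes * n_donors, meanlog = m, sdlog = s),
                            n_genes, n_donors)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate negative-binomial counts for one donor and gene
#'
#' Counts follow `NB(r, sigma)` with `r = mu*sigma/(1-sigma)` successes and
#' success probability `sigma` (counting failures), which fixes
#' `E[count] = mu` independent of `sigma` and `Var[count] = mu/sigma`.
#'
#' @param mu Mean count (> 0).
#' @param sigma Success probability in (0, 1).
#' @param n_cells Number of draws.
#' @param seed Optional seed.
#' @return Integer vector of length `n_cells`.
#' @export
simulate_counts <- function(mu, sigma, n_cells, seed = NULL) {
  if (!(sigma > 0 && sigma < 1)) abort("`sigma` must lie in (0, 1).")
  stopifnot(mu > 0)
  draw <- function() rnbinom(n_cells, size = mu * sigma / (1 - sigma),
                             prob = sigma)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Simulate the per-donor count matrices of one set. Returns a cells x genes
# matrix plus donor/group vectors.
simulate_set <- function(sc, n_cells_per_donor) {
  nd <- sc$n_patients + sc$n_controls
  groups <- rep(c("patient", "control"), c(sc$n_patients, sc$n_controls))
  donors <- sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                    c(seq_len(sc$n_patients), seq_len(sc$n_controls)))
  mu <- sample_donor_means(sc$genes_per_set, nd, sc$m, sc$s)
  blocks <- vector("list", nd)
  for (d in seq_len(nd)) {
    sig <- if (groups[d] == "patient") sc$sigma1 else sc$sigma2
    cnt <- vapply(seq_len(sc$genes_per_set), function(g) {
      simulate_counts(mu[g, d], sig, n_cells_per_donor[d])
    }, numeric(n_cells_per_donor[d]))
    blocks[[d]] <- cnt
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- sprintf("gene%03d", seq_len(sc$genes_per_set))
  list(values = values,
       donor = rep(donors, n_cells_per_donor),
       group = rep(groups, n_cells_per_donor),
       donors = donors, groups = setNames(groups, donors))
}

scenario_cells <- function(sc) {
  nd <- sc$n_patients + sc$n_controls
  if (length(sc$cells_per_donor) == nd) return(as.integer(sc$cells_per_donor))
  stopifnot(length(sc$cells_per_donor) == 2)
  sample(sc$cells_per_donor[1]:sc$cells_per_donor[2], nd, replace = TRUE)
}

#' Run the proposed DE test on one simulated scenario
#'
#' Simulates `n_sets` sets of `genes_per_set` genes under the scenario's
#' generative law (the cells-per-donor layout is drawn once per scenario and
#' shared across sets), runs the median-pairwise-Wilcoxon permutation test
#' on each set, and returns per-gene p-values. No expression filter is
#' applied unless `min_expr_frac > 0`.
#'
#' @param sc A [simulation_scenario()].
#' @param min_expr_frac Expression filter passed to the score table.
#' @param max_exact Permutation budget (see [permutation_pvalue()]).
#' @return Tibble with `set`, `gene`, `statistic`, `p_value`.
#' @export
run_scenario <- function(sc, min_expr_frac = 0, max_exact = 200000) {
  stopifnot(inherits(sc, "simulation_scenario"))
  withr::with_seed(sc$seed, {
    ncell <- scenario_cells(sc)
    purrr::map_dfr(seq_len(sc$n_sets), function(s) {
      dat <- simulate_set(sc, ncell)
      tab <- pairwise_scores_matrix(dat$values, dat$donor, dat$group,
                                    min_expr_frac = min_expr_frac)
      res <- permutation_pvalue(tab, max_exact = max_exact,
                                seed = sc$seed + s)
      tidy(res) |>
        mutate(set = s, .before = 1) |>
        select("set", "gene", "statistic", "p_value")
    })
  })
}

#' False negative / false positive rate of a p-value set
#'
#' Case I (planted distribution difference): FNR = percentage of genes with
#' `p > alpha`. Case II (null): FPR = percentage of genes with `p < alpha`.
#' `p == alpha` counts toward neither rejection.
#'
#' @param pvals Numeric p-values.
#' @param case `"I"` (report FNR) or `"II"` (report FPR).
#' @param alpha Significance level.
#' @return Percentage in \[0, 100\].
#' @export
error_rates <- function(pvals, case = c("I", "II"), alpha = 0.05) {
  case <- match.arg(case)
  if (!length(pvals)) abort("Empty p-value vector.")
  if (case == "I") 100 * mean(pvals > alpha) else 100 * mean(pvals < alpha)
}

#' Default dispersion grids for the benchmark
#'
#' Nine `sigma` settings spanning \[0.1, 0.9\]. The `"equal"` grid
#' (`sigma1 == sigma2`) probes the null; the `"unequal"` grid plants pure
#' dispersion differences, ordered from clearly separated pairs to similar
#' ones, with the ninth combination using the extreme value 0.086 where
#' heavy zero-inflation itself marks the distribution.
#'
#' @param case `"equal"` or `"unequal"`.
#' @return Tibble with `combination`, `sigma1`, `sigma2`.
#' @export
default_sigma_grid <- function(case = c("equal", "unequal")) {
  case <- match.arg(case)
  if (case == "equal") {
    s <- seq(0.1, 0.9, by = 0.1)
    tibble(combination = seq_along(s), sigma1 = s, sigma2 = s)
  } else {
    tibble(
      combination = 1:9,
      sigma1 = c(0.1, 0.1, 0.2, 0.3, 0.2, 0.4, 0.5, 0.7, 0.086),
      sigma2 = c(0.9, 0.7, 0.8, 0.9, 0.6, 0.6, 0.7, 0.9, 0.3)
    )
  }
}

#' Sample-size presets for the benchmark
#'
#' Three synthetic donor layouts standing in for cohort-derived cell-count
#' combinations: all use 9 patients and 6 controls and differ in the
#' per-donor cell-count range.
#'
#' @return Named list of `cells_per_donor` ranges.
#' @export
sample_size_presets <- function() {
  list(combo1 = c(300, 800), combo2 = c(100, 500), combo3 = c(30, 100))
}

#' Build a scenario grid from a dispersion table
#'
#' @param sigma_grid Tibble with `sigma1`, `sigma2` (e.g.
#'   [default_sigma_grid()]).
#' @param seed Base seed; scenario `i` uses `seed + i`.
#' @param ... Passed to [simulation_scenario()].
#' @return List of scenarios.
#' @export
scenario_grid <- function(sigma_grid, seed = 1, ...) {
  purrr::pmap(list(sigma_grid$sigma1, sigma_grid$sigma2,
                   seq_len(nrow(sigma_grid))),
              function(s1, s2, i) {
                simulation_scenario(s1, s2, seed = seed + i, ...)
              })
}

# edgeR arm of the benchmark. Counts are aggregated per donor (summed) by
# default: treating every cell as an independent sample ignores the donor
# structure and badly miscalibrates the test (see the methods vignette).
edger_pvalues <- function(values, donor, group, samples = c("donor", "cell")) {
  samples <- match.arg(samples)
  if (!requireNamespace("edgeR", quietly = TRUE)) {
    abort("edgeR is not installed.")
  }
  if (samples == "donor") {
    donors <- unique(donor)
    y <- vapply(donors, function(d) {
      colSums(values[donor == d, , drop = FALSE])
    }, numeric(ncol(values)))
    grp <- factor(group[match(donors, donor)])
  } else {
    y <- Matrix::t(values)
    grp <- factor(group)
  }
  d <- edgeR::DGEList(counts = as.matrix(y), group = grp)
  d <- edgeR::calcNormFactors(d)
  d <- suppressMessages(edgeR::estimateDisp(d))
  et <- edgeR::exactTest(d)
  setNames(et$table$PValue, rownames(et$table))
}

#' Run the full simulation benchmark
#'
#' For every scenario in `grid` and every simulated set, runs the requested
#' methods and records the per-set error rate: FPR for case-II (null)
#' scenarios, FNR for case-I scenarios. The same simulated data feed both
#' methods. If edgeR is unavailable its arm is skipped with a warning and
#' the proposed-method rows are still produced.
#'
#' @param grid List of [simulation_scenario()]s (see [scenario_grid()]).
#' @param methods Any of `"median_wilcoxon_perm"`, `"edger"`.
#' @param alpha Significance level for the rates.
#' @param edger_samples `"donor"` (aggregate counts per donor; default) or
#'   `"cell"` (every cell a sample).
#' @param max_exact Permutation budget for the proposed method.
#' @return A `benchmark_result` tibble: one row per (scenario, set, method)
#'   with `combination`, `sigma1`, `sigma2`, `case`, `set`, `method`,
#'   `rate_type`, `rate`.
#' @export
run_benchmark <- function(grid,
                          methods = c("median_wilcoxon_perm", "edger"),
                          alpha = 0.05, edger_samples = "donor",
                          max_exact = 200000) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("edger" %in% methods && !requireNamespace("edgeR", quietly = TRUE)) {
    warn("edgeR unavailable; its benchmark arm is skipped.")
    methods <- setdiff(methods, "edger")
  }
  rows <- purrr::imap_dfr(grid, function(sc, i) {
    withr::with_seed(sc$seed, {
      ncell <- scenario_cells(sc)
      purrr::map_dfr(seq_len(sc$n_sets), function(s) {
        dat <- simulate_set(sc, ncell)
        out <- list()
        if ("median_wilcoxon_perm" %in% methods) {
          tab <- pairwise_scores_matrix(dat$values, dat$donor, dat$group)
          p <- tidy(permutation_pvalue(tab, max_exact = max_exact,
                                       seed = sc$seed + s))$p_value
          out$median_wilcoxon_perm <- p
        }
        if ("edger" %in% methods) {
          out$edger <- tryCatch(
            edger_pvalues(dat$values, dat$donor, dat$group,
                          samples = edger_samples),
            error = function(e) {
              warn(paste0("edgeR arm failed: ", conditionMessage(e)))
              NULL
            })
        }
        purrr::imap_dfr(out, function(p, meth) {
          if (is.null(p)) return(tibble())
          tibble(combination = i, sigma1 = sc$sigma1, sigma2 = sc$sigma2,
                 case = sc$case, set = s, method = meth,
                 rate_type = if (sc$case == "I") "fnr" else "fpr",
                 rate = error_rates(p, sc$case, alpha))
        })
      })
    })
  })
  class(rows) <- c("benchmark_result", class(rows))
  rows
}

#' @describeIn run_benchmark Mean rate per method and rate type.
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  x |>
    group_by(.data$method, .data$rate_type) |>
    summarise(mean_rate = mean(.data$rate), n_sets = dplyr::n(),
              .groups = "drop")
}

#' @describeIn run_benchmark Heatmap of mean rates over the dispersion grid.
#' @param object A `benchmark_result`.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  object |>
    group_by(.data$combination, .data$sigma1, .data$sigma2, .data$method,
             .data$rate_type) |>
    summarise(rate = mean(.data$rate), .groups = "drop") |>
    ggplot(aes(x = factor(.data$combination), y = .data$method,
               fill = .data$rate)) +
    geom_tile() +
    facet_wrap(~.data$rate_type) +
    scale_fill_viridis_c(limits = c(0, 100)) +
    labs(x = "dispersion combination", y = NULL, fill = "%") +
    theme_minimal()
}
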