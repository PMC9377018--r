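---
title: "Patient-aware differential expression and annotation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-aware differential expression and annotation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwsc)
library(dplyr)
```

# The problem

Single-cell RNA-seq cohort studies compare expression between patient groups
(here: patients versus controls, e.g. COPD versus healthy donors in
bronchoalveolar lavage), but cells from one donor are not independent
replicates. Tests that pool cells across donors treat thousands of correlated
cells as independent observations and produce wildly anti-conservative
p-values (pseudoreplication). `pwsc` implements a donor-aware,
distribution-free alternative, together with the simulation machinery that
calibrates it, donor-level gene-set statistics, reference-based cluster
annotation, and machine-learning label consolidation — all runnable on seeded
synthetic data.

# The differential-expression test

For one gene in one cell cluster, let $x_{d}$ denote the per-cell normalized
expression values of donor $d$. For every unordered donor pair we compute the
rank-biserial Wilcoxon score

$$s(a, b) = \frac{2U_{ab}}{n_a n_b} - 1 \in [-1, 1],$$

where $U_{ab}$ counts cell pairs with $x_a > x_b$ plus half the ties. The
test statistic is the median of $s(p, c)$ over all ordered
(patient, control) pairs, $T \in [-1, 1]$. Its null distribution is obtained
by permutation: every reassignment of the $n_P + n_C$ donors into groups of
the same sizes is enumerated (`choose(n_P + n_C, n_P)` assignments; 5,005
for the default 9 + 6 layout), and the two-sided p-value is the fraction of
assignments with $|T_{\text{perm}}| \ge |T_{\text{obs}}|$.

Design choices worth stating explicitly:

* **Score normalization.** The pairwise "Wilcoxon score" is the
  rank-biserial correlation: bounded, signed, independent of the two donors'
  cell counts, which is what makes a *median over donor pairs* and a fixed
  cutoff ($|T| \ge 0.75$) meaningful.
* **Two-sidedness.** "Equal or more extreme" is read as $|T|$; a one-sided
  variant would only differ in the direction convention.
* **The identity assignment is counted**, so $p \ge 1/n_{\text{perm}}$ and
  the test is (slightly) conservative by construction.
* **Exact enumeration by default**; above `max_exact` (default 200,000) a
  seeded Monte-Carlo subsample that always contains the observed assignment
  is used, and the number of assignments is reported.
* **Ties** are handled with the 1/2-count convention throughout; no
  continuity correction.
* **Precomputation.** Pair scores are computed once per gene; permutations
  only re-index and re-sign them, so the 5,005-assignment enumeration costs
  about a second per 50-gene set.
* **Tie comparisons** in the p-value use a $10^{-9}$ guard: scores are
  rationals with small denominators, so the guard can only protect exact
  ties from last-bit rounding, never merge distinct values.
* **Filters.** Donors without cells in a cluster are dropped first; genes
  expressed in fewer than 10% of the cluster's cells are disregarded. Gene
  selection uses the inclusive cutoff $|T| \ge 0.75$, sorts ascending by
  p-value (ties: $|T|$ descending, then symbol) and keeps the top 300.

Because the statistic is rank-based, all results are invariant to strictly
monotone transforms of expression, so the test behaves identically on raw
counts and log-CPM values.

```{r de-example}
spec <- fixture_spec(n_patients = 4, n_controls = 4, n_de_genes = 10,
                     seed = 42)
m <- log_cpm_normalize(qc_filter(synth_grouped_counts(spec)))
res <- permutation_pvalue(pairwise_scores(m, "c0"), seed = 1)
glance(res)
tidy(res) |> arrange(p_value) |> head(5)
```

# The simulation benchmark

The test's operating characteristics are measured on negative-binomial
counts with donor-level heterogeneity. Per gene and donor, a mean is drawn
from a shared log-normal law, $\mu \sim \mathrm{LogNormal}(m = 1, s = 0.15)$,
and cells are drawn as

$$\text{counts} \sim \mathrm{NB}(h(\mu, \sigma), \sigma), \qquad
h(\mu, \sigma) = \frac{\mu \sigma}{1 - \sigma},$$

with $h$ the number of successes and $\sigma$ the success probability
(counting failures). This parameterization pins the mean at $\mu$ for every
$\sigma$ and puts all group differences into the dispersion:
$\mathrm{Var} = \mu / \sigma$. Case I uses $\sigma_1 \ne \sigma_2$ (a pure
distribution-shape difference at equal means); case II uses
$\sigma_1 = \sigma_2$ (the null). Per dispersion combination, three sets of
50 genes are simulated; FNR is the percentage of case-I genes with
$p > 0.05$ and FPR the percentage of case-II genes with $p < 0.05$
(p-values exactly at $\alpha$ count toward neither).

Choices the benchmark fixes once:

* **Donor layout**: 9 patients, 6 controls, each with a cell count drawn
  uniformly from [100, 500]. The cohort the layout emulates does not publish
  its per-cluster cell counts, so these are package defaults; three named
  presets (`sample_size_presets()`) vary the cell-count range and the whole
  layout is configurable.
* **Dispersion grids** (`default_sigma_grid()`): the null grid is
  $\sigma_1 = \sigma_2 \in \{0.1, \dots, 0.9\}$; the case-I grid spans
  nine pairs in $[0.1, 0.9]$ ordered from clearly separated to similar,
  with the ninth using $\sigma_1 = 0.086$, where heavy zero-inflation
  itself distinguishes the distributions.
* **edgeR comparison arm.** Counts are summed per donor and the donors are
  the edgeR samples (TMM normalization, `exactTest`). We deliberately do
  *not* pass individual cells as samples: in a pilot of that design the
  donor random effect inflated the null FPR to roughly 50% while the
  common-dispersion fit absorbed the case-I signal (FNR near 6%) — i.e. the
  cells-as-samples design answers a different question badly. The
  donor-aggregated design reproduces the expected behaviour of a
  mean-difference test here: calibrated FPR under the null and >90% FNR in
  case I, because the two groups differ only in distribution shape, which
  pseudobulk means cannot see. `edger_samples = "cell"` remains available.

```{r bench-example, eval = FALSE}
grid <- scenario_grid(default_sigma_grid("equal"), seed = 1)
bench <- run_benchmark(grid, methods = c("median_wilcoxon_perm", "edger"))
glance(bench)
```

At this scale (1,350 null genes) the mean FPR of the permutation test lands
within three binomial standard errors of the 5% nominal level, and so does
the donor-aggregated edgeR arm; `scripts/acceptance.R` recomputes exactly
these quantities from scratch.

# Gene-set distance on donor pseudobulk

To ask which functional gene sets separate the groups, cells are averaged
per donor within a cluster (clusters qualify only if *every* donor has at
least 10 cells in them; genes expressed in under 5% of the cluster's cells
are excluded). For a gene set $S$ present with at least 3 genes, all
pairwise donor distances are computed on the profile restricted to $S$, and

$$\text{gene set distance} =
\frac{\overline{d}_{\text{all pairs}}}
     {\overline{d}_{\text{within patients}} + \overline{d}_{\text{within controls}}}.$$

The numerator includes within-group pairs: under exchangeability all three
means coincide and the ratio sits at 0.5, which makes the null baseline
interpretable and values near or above 1 indicate that between-group
separation dominates. Single-donor groups leave a within-group mean
undefined, so two donors per group are required; a zero denominator with a
positive numerator is reported as "perfectly separating" rather than ranked
as infinite, and 0/0 as degenerate. Euclidean is the default metric, with
Manhattan as the robustness option (rankings on the same fixture agree with
Spearman correlation > 0.8). Word-frequency summaries of the top percentile
of ranked set names drop collection prefixes, stopwords and pure numbers.

# Reference-based cluster annotation

Two annotators label *cluster mean* expression vectors against a reference:

* **GenSigPro** regresses the cluster vector jointly on all reference
  cell-type signatures (OLS with intercept — a Gaussian-family GLM) over the
  shared genes. The cluster gets the label of the largest coefficient if it
  is positive with uncorrected $p < 0.05$, otherwise "Unassigned".
  Noiseless mixtures of signatures are recovered exactly, and the sign
  decision is invariant to positive rescaling of the cluster vector.
* The **iterative correlation annotator** scores every cell type by the
  0.8-quantile of Spearman correlations between the cluster vector and that
  type's reference samples, computed on discriminating genes (per ordered
  type pair, the top genes by median-signature difference; budget
  $\max(\lfloor 500 \cdot (2/3)^{\text{iter}} \rfloor, 5)$ per pair). The
  lowest-scoring type is dropped and the gene set recomputed until one type
  survives; a final score below 0.1 yields "unknown". The per-pair gene
  budget matters: with only a few dozen genes the Spearman null standard
  deviation ($\approx 1/\sqrt{n}$) would let random vectors clear the 0.1
  threshold, so the default budget is in the hundreds (configurable). When
  a reference has one vector per type, the quantile degenerates to that
  vector's correlation.

Uncertainty for either annotator comes from 100 bootstrap datasets obtained
by resampling cells with replacement *within each cluster* (preserving
cluster sizes, so cluster identity stays meaningful); reported per cluster
are the point label and the bootstrap label frequencies.

# Label consolidation and four-step cluster annotation

Three per-cell annotations, harmonized to a common label standard, train one
gradient-boosted tree classifier: each cell's feature vector (raw counts of
the top-variance genes, default cap 2,000, plus tissue indicator, expressed
genes, total counts, mitochondrial percentage) appears three times, once per
source label. Cross-validation is 3-fold and *grouped by cell* — all three
rows of a cell land in the same fold — so no cell influences the model that
labels it. Boosting uses 100 trees of depth 3 with learning rate 0.1 and
row/column subsampling of 0.8 per tree; without subsampling, perfectly
separable synthetic data lets every round split on the same single marker
gene, and cells with one atypical value at that gene misclassify. All
hyperparameters are exposed.

Cluster-level annotation then takes the majority consolidated label per
cluster with its purity; clusters below 0.5 purity are flagged as mixed
("contaminating" cells), and a cluster is confirmed when at least one
canonical marker of its majority label passes the marker-gene screen
(cluster-versus-rest Wilcoxon with tie-corrected normal approximation,
Bonferroni-adjusted $p < 0.001$, natural-log fold change of expm1-space
means $\ge 0.4$, expressed in $\ge 50\%$ of the cluster's cells).

# Assay metrics

Two closed-form helpers round out the workflow. The flow-cytometry effect
size references each marker to its fluorescence-minus-one control,
$(\bar{x}_{\text{full}} - \bar{x}_{\text{FMO}}) /
\sqrt{(s^2_{\text{full}} + s^2_{\text{FMO}})/2}$, absorbing donor-specific
autofluorescence. The extracellular-flux metrics are phase differences of
oxygen consumption against rotenone/antimycin-A-inhibited respiration
(basal, maximal, proton leak; ATP-linked respiration is exposed as basal
minus proton leak as a derived convenience). Phase summaries default to the
mean of the measurement cycles per phase (`method = "last"` uses the final
cycle); whether a published trace uses first-cycle or cycle-mean baselines
is rarely stated, and the choice is configurable for that reason.

# What the synthetic data does and does not show

The generators reproduce exactly the structure the methods assume:
donor-structured NB counts with log-normal donor means, dispersion-only
group differences, clusters drawn from planted signatures, gene sets with a
planted separating member. They do *not* model library-size gradients,
dropout beyond NB zeros, batch effects, doublets, or correlated gene
modules. Green tests therefore demonstrate correctness of the statistical
machinery under its own model, not robustness to every artefact of real
scRNA-seq data — the QC, normalization and donor-aware design are the
defences against those, and the controlled-access cohort data needed to
reproduce the biological findings are deliberately out of scope.

Problem sizes used by the test-suite and acceptance computations — 50-gene
sets, 9 + 6 donors with 100–500 cells, 27 sets per grid, a 3,000-cell
consolidation fixture — are the package's chosen desk-scale defaults; every
generator accepts larger values.

# Known limitations

* The permutation p-value's resolution is $1/n_{\text{perm}}$; with few
  donors the smallest achievable p-value may exceed conventional
  significance levels, which is a property of the design, not a bug.
* `qc_filter` applies one pass (gene filter, then cell filters); in the
  rare case that removing cells drops a gene below the 3-cell rule, a
  second pass would remove it. The single pass is documented and
  deterministic.
* The gene-set distance requires at least two donors per group and treats
  perfectly-separating degenerate sets as unrankable rather than infinite.
* The consolidation classifier inherits gradient boosting's indifference to
  monotone feature transforms but not its robustness to label noise beyond
  what 3-fold majority structure provides.
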