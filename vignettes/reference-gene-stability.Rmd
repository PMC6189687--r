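---
title: "Choosing stable reference genes for RT-qPCR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable reference genes for RT-qPCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

## The problem

Relative quantification by RT-qPCR reports a target gene's expression as a
fold change against one or more reference ("housekeeping") genes measured in
the same samples. The whole construction stands or falls with the assumption
that the reference gene is itself stably expressed across the experimental
conditions. Under a cytotoxic perturbation — here the motivating system is
Busulfan injury of cultured microvascular endothelial cells observed over a
0–72 h time course — classical references such as *actb* or *gapdh* can
drift substantially, and normalizing against them distorts every downstream
conclusion.

`rgstab` implements the standard toolkit for auditing candidate references
from a matrix of quantification cycles (Cp/Ct; genes in rows, samples in
columns): four stability estimators with different operating logic, a
consensus ranking that aggregates them, the dilution-series efficiency
computation, and reference-normalized fold-change series for targets. A
seedable simulator generates Cp datasets with known stable/unstable labels
so that the whole pipeline can be validated by parameter recovery.

One cycle on the Cp scale is one doubling of template under perfect
efficiency, so Cp is already a log2-scale quantity; every method below
works on cycles or on log ratios of relative quantities.

## Data model and gene filtering

A `cp_matrix` couples the Cp grid with a sample sheet (`sample_id`, `group`,
`timepoint_h`, `replicate`). Cells that did not amplify (`"Undetermined"`,
empty) become missing values at read time.

Candidates are screened by `filter_genes_by_cp_range()`: genes whose mean Cp
exceeds 30 cycles (too scarce for reliable quantification) or falls below 15
(outside the quantitative range) are excluded, with strict inequalities at
the bounds. A gene with any missing Cp in treated samples is also excluded:
all four estimators assume complete rows, and a dropout under treatment is
itself strong evidence against a candidate. The mean used is the arithmetic
mean of non-missing Cp.

## The four estimators

### BestKeeper

Each gene gets descriptive statistics (geometric and arithmetic mean Cp,
extremes, dispersion, CV%). The dispersion is the mean absolute deviation
about the arithmetic mean by default — the convention of the original
BestKeeper tool — with a sample-SD option (`dispersion = "sd"`); CV% is
always `100 * dispersion / arithmetic mean`, so the identity between the
reported columns holds under either choice. The *index* is the per-sample
geometric mean of Cp over all retained genes, and each candidate is scored
by the Pearson correlation of its Cp profile with that index (two-sided
p-value from the exact t transform, floored at 0.001 for display only).
Genes are ranked by descending `r`; the sign is deliberately kept, since a
gene anti-correlated with the panel consensus is unstable by construction.
The index is built over *all* retained genes rather than a best-k subset —
a single index pass is the variant that matches the published workflow this
package is patterned on.

### geNorm

Cp values are converted to relative quantities
\(Q(g,s) = (1+E_g)^{Cp_{\min}(g) - Cp(g,s)}\), anchored on each gene's
minimum Cp (any anchor cancels in ratios; the minimum keeps \(Q \le 1\)).
The default efficiency is \(E = 1\) (perfect doubling) with a per-gene
override. The stability measure for gene \(g\) is
\[
M_g = \frac{1}{G-1} \sum_{k \ne g} \mathrm{SD}_s\!\left[\log_2
  \frac{Q(g,s)}{Q(k,s)}\right],
\]
with the n−1 SD denominator. Ranking is by stepwise exclusion: remove the
highest-M gene, recompute on the survivors, repeat until two genes remain;
those two share rank 1 (their M values are identical by construction, so
they cannot be separated). A tie at removal drops the later gene in input
order, and every tie is logged in the result.

The pairwise-variation curve takes \(NF_n(s)\) as the geometric mean of
\(Q\) over the \(n\) most stable genes and
\(V_{n/n+1} = \mathrm{SD}_s[\log_2(NF_n/NF_{n+1})]\) for
\(n = 2 \dots G-1\). The number of reference genes to use is the smallest
\(n\) with \(V \le 0.15\) (the conventional cutoff, configurable); if the
whole curve stays above the cutoff all genes are suggested, with a warning.

### NormFinder-style model-based estimation

Within each sample group the model is \(y_{ij} = \mu_i + b_j + e_{ij}\) with
gene-specific noise variance \(\sigma_i^2\). The two-way residuals
\(r_{ij} = y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \bar y_{\cdot\cdot}\)
give \(\hat s_i^2 = \sum_j r_{ij}^2/(n_g-1)\), whose expectation is
\((1 - 2/G)\,\sigma_i^2 + \bar\sigma^2/G\) because the per-sample mean
contains a share of each gene's own noise. Solving the moment equations
yields the corrected estimator
\[
\hat\sigma_i^2 = \left(\hat s_i^2 - \frac{\bar s^2}{G-1}\right)
  \frac{G}{G-2},
\]
clamped at zero when negative (clamp events are counted in the result).

The inter-group deviation \(d_{ig}\) is the gene's group mean centered on
the group's across-gene mean and then on the gene's own across-group mean —
so adding a constant to a gene's whole row cancels exactly. Deviations are
shrunk toward zero by the variance ratio
\(\tilde d_{ig} = d_{ig}\,\hat\tau^2 / (\hat\tau^2 + \hat\sigma_i^2/n_g)\),
with \(\hat\tau^2 = \max\!\big(0, \sum_{ig} d_{ig}^2 / ((G-1)(K-1)) -
\overline{\hat\sigma^2/n}\big)\) a method-of-moments estimate of the true
between-group variance. The stability value is
\[
\rho_i = \frac{1}{K} \sum_g \left( |\tilde d_{ig}| +
  \sqrt{\hat\sigma_i^2 / n_g} \right),
\]
lower = more stable. For a gene set the shrunken deviations are averaged
(opposite signs cancel, which is why a pair can score better than the best
single gene) and the SE term pools variances; the best pair is found by
exhaustive search over all pairs.

The default grouping is control (0 h) versus treated (12–72 h). The
experimental design behind this package never fixed its grouping publicly,
so the scheme is an explicit argument (`control_vs_treated`,
`by_group_column`, `by_timepoint`, or `NULL` for the ungrouped variant,
which reduces to the residual-SD ordering).

### Comparative delta-delta-Ct statistic

For each sample, a gene's \(\Delta Ct\) is taken against the per-sample
minimum Ct across genes (the most abundant transcript acts as the
within-sample control, cancelling loading differences). The gene with the
lowest mean \(\Delta Ct\) anchors the comparison; per-sample folds
\(2^{\Delta Ct_g(s) - \overline{\Delta Ct}_{ctrl}}\) are averaged into the
mean fold difference, and the true fold difference is its log2. Ranking is
by descending mean fold.

Two caveats are documented deliberately. First, published tables computed
with this procedure elsewhere are not internally reconstructible (their
printed ddCt column is inconsistent with their fold column); the recipe
implemented here is the one whose fold column propagates consistently into
the published consensus ranking, and the identities `variance = sd^2` and
`true_fold = log2(mean_fold)` hold at full precision in this
implementation. Second, the mean of per-sample folds is convex in
\(\Delta Ct\), so the statistic rises with both a gene's offset from the
anchor and its variability; it is a descriptive index, not a variance
decomposition, and it enters the consensus as one voice among four.

## Consensus

Each method contributes a competition ranking (ties share the minimum rank;
the next rank skips — "1224"). The comprehensive score is the unweighted
geometric mean of the four ranks, and the final order is the competition
ranking of those scores. The geometric mean is the only aggregation that
reproduces, row for row, the published consensus table shipped with the
package (`published_stability_tables("ranks")`), which is the package's
deterministic cross-check.

## Standard curves

`fit_standard_curve()` is an OLS fit of Cp against log10 template amount;
the efficiency is \(E = 10^{-1/A} - 1\) for slope \(A < 0\), so the
perfect-doubling slope \(-1/\log_{10} 2 \approx -3.322\) gives
\(E = 1\). Published assay tables in this field sometimes print the formula
as \(\%E = 10^{-1/A} \cdot 100\); that form does not match the same tables'
printed values, while \(10^{-1/A} - 1\) does, so the subtractive form is
the default and the percent-of-doubling form sits behind
`percent_of_doubling = TRUE`. The bundled
`published_stability_tables("standard_curves")` flags which published rows
are internally consistent; the inconsistent rows (physically impossible
slopes near −0.3, or efficiencies irreconcilable with their slopes) are
excluded from every check.

## The simulator

`simulate_cp()` draws Cp values from an additive model on the cycle scale:
baseline + gene drift (linear in time) + a shared per-sample shift + a
gene-specific perturbation + technical well noise, all Gaussian. The
additive-in-cycles choice is exact for multiplicative expression changes;
no noise model was ever published for the motivating dataset, so Gaussian
is the parsimonious default.

The default panel emulates the published screen's structure: seven highly
expressed genes (21–24 cycles) and six moderate ones (26–28 cycles); a
shared injury trend of about 3 cycles over 72 h for the stable genes
(matching the published per-gene min–max spans of 5–10 cycles once the
1.5-cycle shared loading shift is added); and three genes (`gapdh`, `tbp`,
`ubc`) made unstable by decoupled drift and elevated perturbation SD,
mirroring the genes the published consensus ranked worst. Under these
defaults the long-run per-gene CV% of Cp falls inside the published
4.32–9.66% band, which the test suite verifies over 200 seeded datasets.

The shared shift is the dominant spread: "stability" in every estimator
means tracking the panel consensus, so the simulator makes the consensus
signal (shared shift + common trend) large relative to gene-specific noise
for stable genes. What the simulator does *not* emulate: amplification
kinetics and fluorescence thresholds, primer-dimer artifacts,
heteroskedastic late-cycle noise, RNA degradation interacting with
transcript length, and non-Gaussian dropout mechanisms. Passing recovery
tests therefore demonstrate the estimators' correctness and their joint
behavior under the assumed covariance structure, not robustness to every
pathology of real plates.

## Fold-change series

`fold_change_series()` computes \(\Delta Ct = Cp_{target} - Cp_{ref}\)
per sample, anchors on the mean \(\Delta Ct\) of the control-timepoint
replicates, and reports per-timepoint mean fold \(2^{-\Delta\Delta Ct}\)
with SD and SEM (figures in this field conventionally show SEM; tables show
SD — both are stored) plus a two-sided Welch t-test on log2 folds against
the control replicates (no named test accompanies published significance
stars, and Welch on log folds is the defensible default; the p-value is
`NA` when the data are constant and the test undefined).

One subtlety is worth spelling out. Adding a constant \(c\) to the
reference's Cp shifts every \(\Delta Ct\) *and* the control anchor by
\(-c\), so the anchored fold is exactly invariant — constant reference
offsets are harmless by design. The familiar \(2^c\) distortion law applies
to the *unanchored* relative quantity \(2^{-\Delta Ct}\), which is stored
per sample alongside the fold; a reference that *drifts* by \(c(t)\) cycles
(rather than shifting constantly) inflates anchored folds by exactly
\(2^{c(t)}\), which is the mechanism that makes unstable references
dangerous and is asserted in closed form in the tests.

## Numerical and design choices

- Log base 2 throughout; sample SDs use the n−1 denominator.
- geNorm removal ties drop the later gene in input order and are logged;
  the final pair shares rank 1.
- Negative variance estimates in the model-based method are clamped at 0
  and counted.
- Relative-quantity anchor is the per-gene minimum Cp; BestKeeper's p-values
  are floored at 0.001 in displays only; human-readable pipeline reports
  round to 2 decimals while machine outputs keep full precision.
- Competition ("1224") ranking everywhere; undefined statistics (e.g. a
  zero-variance gene's correlation) are flagged and ranked last.
- `run_pipeline()` writes every artifact with an MD5 manifest and a JSON
  summary recording the choices actually taken (grouping, ties, clamps),
  and is byte-deterministic for a fixed input.

Problem sizes used by the validation suite are chosen to make the checks
sharp but quick: 5-gene × 12-sample matrices for oracle equivalence
(tolerance 1e−10), 50 seeded 13-gene datasets for consensus recovery
(requiring all three planted unstable genes among the five worst in at
least 90%), 100–200 seeded replicates for distributional properties.

## Known limitations

- The estimators require complete Cp rows; there is no imputation. Genes
  with dropouts are excluded, which is conservative.
- The delta-delta-Ct statistic inherits the convexity caveat above.
- No efficiency-corrected (Pfaffl-type) target quantification; fold changes
  assume perfect doubling for both target and reference.
- No confidence intervals on stability values; ranking uncertainty must be
  assessed by resampling or simulation (the simulator makes this easy).
- BestKeeper's per-gene regression diagnostics against the index are not
  implemented — only the correlation ranking the consensus consumes.
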