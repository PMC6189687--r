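# rgstab — reference-gene stability analysis for RT-qPCR

Relative RT-qPCR quantification reports a target gene's expression as a
fold change against a reference ("housekeeping") gene measured in the same
samples — valid only if the reference is itself stably expressed under the
experimental conditions. Under cytotoxic perturbations (the motivating
system is Busulfan injury of cultured microvascular endothelial cells over
a 0–72 h time course) the classical references *actb* and *gapdh* can drift
badly, and an unstable reference that gains `c` cycles distorts every fold
change by `2^c`.

`rgstab` is for bench scientists and analysts who need to audit candidate
reference genes from a quantification-cycle (Cp/Ct) table before
normalizing anything. It implements the field's standard toolkit:

- **BestKeeper**: per-gene descriptives (geometric/arithmetic mean Cp,
  min/max, dispersion, CV%) and the Pearson correlation `r` of each gene
  with the per-sample geometric-mean index; rank by descending `r`.
- **geNorm**: stability measure
  `M_g = mean_k SD_s[log2(Q_g/Q_k)]` on relative quantities
  `Q = (1+E)^(Cp_min − Cp)`, stepwise exclusion of the highest-M gene, and
  the pairwise-variation curve `V(n/n+1)` with the 0.15 cutoff for choosing
  how many references to use.
- **NormFinder-style model-based estimation**: per-group variance
  decomposition with bias-corrected intra-group variances and shrunken
  inter-group deviations; stability
  `ρ_i = mean_g(|d̃_ig| + sqrt(σ̂²_ig/n_g))`, plus the best two-gene
  combination by exhaustive search.
- **Comparative ΔΔCt statistic**: per-sample ΔCt against the most abundant
  gene, folds `2^−ΔΔCt` anchored on the lowest-mean-ΔCt gene, ranked by
  descending mean fold difference.
- **Consensus**: unweighted geometric mean of the four competition ranks
  ("1224" ties), ascending order = final stability ranking.

Around the core: dilution-series standard curves with amplification
efficiency `E = 10^(−1/A) − 1`, reference-normalized target fold-change
time courses with Welch tests versus the 0 h control, a seedable Cp
simulator with ground-truth stable/unstable labels, and a deterministic
pipeline (`run_pipeline()`) writing TSV/JSON reports with an MD5 manifest.

See the methods vignette
(`vignettes/reference-gene-stability.Rmd`) for the full model
descriptions, assumptions and design decisions.

## Worked example

```r
library(rgstab)

m <- simulate_cp(sim_config(seed = 1))   # 13 genes x 18 samples, 0-72 h
fit <- rg_stability(m)
fit
#> Reference-gene stability analysis: 13 candidates, 18 samples
#>   consensus top 3:  gusb, hmbs, tfrc
#>   best pair (model-based): rplp0 + hmbs
#>   reference genes needed (V <= 0.15): 2

tab <- full_stability_table(fit)
head(tab[order(tab$final_rank),
         c("gene", "bestkeeper_r", "genorm_m", "normfinder_stability",
           "geo_mean", "final_rank")], 5)
#>  gene bestkeeper_r genorm_m normfinder_stability geo_mean final_rank
#>  gusb        0.989   0.0245                0.195     2.06          1
#>  hmbs        0.982   0.0434                0.179     2.34          2
#>  tfrc        0.978   0.0245                0.221     3.56          3
#> ywhaz        0.983   0.0983                0.220     4.74          4
#> rplp0        0.980   0.1117                0.156     5.13          5
```

Reading the output: `bestkeeper_r` is each gene's correlation with the
panel index (closer to 1 = tracks the consensus), `genorm_m` is the mean SD
of pairwise log2 ratios (lower = more stable), `normfinder_stability`
combines intra-group SE with shrunken between-group deviation (lower =
better), `geo_mean` is the geometric mean of the four method ranks, and
`final_rank` orders it ascending. The `V(n/n+1)` curve (in `fit$genorm`)
dropped below 0.15 at n = 2, so two reference genes suffice for this
dataset. The simulator's three planted unstable genes (`gapdh`, `tbp`,
`ubc`) land in the bottom ranks.

Normalizing a target against a chosen reference:

```r
fc <- fold_change_series(m, target = "gapdh", reference = "hmbs")
fc
#> Fold-change series: gapdh normalized to hmbs (control 0 h)
#>  timepoint_h n mean_fold sd_fold sem_fold p_vs_control
#>            0 3      1.00   0.107   0.0617           NA
#>           12 3      1.14   0.155   0.0894       0.2982
#>           24 3      2.37   0.958   0.5530       0.0793
#>           36 3      2.15   1.273   0.7352       0.3087
#>           48 3      2.21   1.351   0.7802       0.2946
#>           72 3      3.35   1.048   0.6051       0.0128
```

(Here the apparent 3-fold "induction" of *gapdh* is exactly the artifact
the package exists to catch: *gapdh* was simulated as an unstable gene, and
its drift away from the stable reference shows up as spurious regulation.)

Standard-curve efficiency from a 10-fold dilution series:

```r
fit_standard_curve(c(0, -1, -2, -3, -4), 19.8 + 3.41 * (0:4), gene = "actb")
#> Standard curve [actb]: Cp = -3.4100 * log10(amount) + 19.8000
#>   R^2 = 1.0000, efficiency E = 0.9645 (n = 5)
```

The package also ships the published summary tables of a 13-gene Busulfan
endothelial screen (`published_stability_tables()`), used as deterministic
cross-checks of the consensus arithmetic, the efficiency formula and the
ΔΔCt identities.

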