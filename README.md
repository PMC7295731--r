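# refstab

Reference-gene stability analysis for RT-qPCR Ct data.

Relative RT-qPCR quantification reports a target gene's expression as a
ratio to one or more reference ("housekeeping") genes assumed constant
across samples. That assumption fails often enough — across life stages,
populations, tissues, treatments — that candidate reference panels are
routinely screened with a standard battery of stability statistics before
any target gene is quantified. refstab implements that battery as a tested
R package:

- **Comparative ΔCt** — a gene's stability is the mean standard deviation
  of its pairwise Ct differences: `stability_i = mean_{k≠i} SD_s(Ct_i − Ct_k)`.
- **geNorm** — average pairwise-ratio stability
  `M_i = mean_{k≠i} SD_s(log2(x_i/x_k))` with stepwise exclusion to a most
  stable pair, normalization factors `NF_n` (per-sample geometric means),
  the pairwise-variation series `V(n,n+1) = SD_s(log2(NF_n/NF_{n+1}))`,
  and the optimal-panel-size rule (smallest n with `V < 0.15`, cutoff
  configurable).
- **NormFinder-style decomposition** — model-based stability
  `ρ(i) = mean_g [ |d̃(i,g)| + √(σ̂²(i,g)/n_g) ]` from an unbiased
  intra-group variance estimator on sample-centered log2 expression and
  empirical-Bayes-shrunk inter-group deviations.
- **BestKeeper** — raw-Ct descriptives: dispersion, CV%, and correlation
  with the per-sample geometric-mean index.
- **RefFinder-style aggregation** — geometric mean of the four methods'
  competition ranks, plus cross-condition rank averaging and
  condition-exclusion sensitivity.
- **Amplification efficiency** — standard-curve fits with
  `E% = (10^(−1/slope) − 1) × 100`.
- **Synthetic Ct generator** — seeded Gaussian Ct model (gene level +
  group effect + sample loading + gene instability + technical noise)
  with known ground-truth stability ordering, so the whole pipeline is
  testable without wet-lab data.

In every statistic, *smaller is more stable*, ties share competition
ranks (1, 1, 3, …), and all logs are base 2. See the methods vignette
(`vignettes/reference-gene-stability.Rmd`) for the models, conventions
and limits.

## Worked example

Simulate a study-like screen (five genes, 12 samples in four groups,
three technical replicates) and rank the candidates:

```r
library(refstab)
sim <- generate_ct_table(default_synthetic_spec(), seed = 7)
sim$table
#> ct_table: 5 genes x 12 samples, 180 Ct entries
#> genes: 18S, actin, GAPDH, UBC, a-tubulin
#> groups: N10 (n=3), S24 (n=3), X8 (n=3), YQ (n=3)

res <- run_analysis(sim$table, quiet = TRUE)
res$delta_ct
#> reference-gene stability (delta_ct):
#>        gene stability rank
#> 1       UBC     0.442    1
#> 2 a-tubulin     0.461    2
#> 3     actin     0.509    3
#> 4     GAPDH     0.544    4
#> 5       18S     0.747    5
res$genorm$optimal
#> optimal number of reference genes: 2 (first V < 0.15)
res$reffinder
#> reference-gene stability (reffinder):
#>        gene stability rank
#> 1       UBC     1.189    1
#> 2 a-tubulin     2.213    2
#> 3     GAPDH     2.378    3
#> 4     actin     3.224    4
#> 5       18S     5.000    5
```

The simulated ground truth makes UBC the most and 18S the least stable
gene (`sim$truth$order`), and the aggregate ranking recovers both
extremes: UBC's RefFinder value 1.189 is the geometric mean of ranks
(1, 2, 1, 1) across ΔCt, BestKeeper, geNorm and NormFinder; 18S is ranked
last by all four (geometric mean 5.000). Two reference genes suffice here
(`V(2,3) < 0.15`). A standard curve:

```r
fit_standard_curve(dilution_series(ct = c(20, 23.32, 26.64),
                                   concentration = c(1, 0.1, 0.01)))
#> standard curve: slope -3.3200, intercept 20.00, r^2 1.0000
#> amplification efficiency: 100.08% (E = 2.0008 per cycle)
```

A Ct rise of ~3.32 cycles per tenfold dilution is perfect doubling, hence
~100% efficiency.

The package also bundles the printed summary tables of a published
five-gene screen in the rice white-tip nematode (`study_ranks()`,
`study_ct_summary()`, `study_v_series()`) as inputs to the rank
arithmetic; `average_ranking(study_rank_matrix("delta_ct"))` reproduces
that screen's cross-condition averages, and
`exclusion_sensitivity(..., exclude = "mixed")` its mixed-population
reanalysis.

## Analysis workflow

`analysis/` holds numbered drivers that run the full study shape over the
package and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # three synthetic conditions
Rscript analysis/02_condition_stability.R      # per-condition bundles
Rscript analysis/03_cross_condition.R          # averages + exclusion sensitivity
Rscript analysis/04_published_rank_arithmetic.R  # rank arithmetic on the bundled tables
```

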