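---
title: "Reference-gene stability analysis: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

Relative RT-qPCR quantification stands or falls with its reference genes: a
target gene's expression is reported as a ratio to genes assumed constant
across the samples being compared. When a "housekeeping" gene drifts with
life stage, population or treatment, every ratio normalized to it drifts
too. refstab implements the four statistics practitioners use to screen
candidate panels from threshold-cycle (Ct) tables — the comparative
delta-Ct method, geNorm, a NormFinder-style variance decomposition and
BestKeeper — plus the RefFinder-style aggregation of their ranks, the
cross-condition rank averaging and condition-exclusion sensitivity used to
compare screens, and a seeded generator of synthetic Ct tables with known
ground truth. This vignette explains the models, every convention the
implementation had to fix, and what the test suite does and does not
establish.

## The data model

All methods consume a `ct_table`: Ct values indexed by gene, sample and
technical replicate, with each sample annotated by one experimental group
(a life stage, a population, a treatment level). Biological replicates are
modeled as distinct samples within their group; technical replicates are
averaged arithmetically before any statistic is computed, because every
downstream method models sample-level variation. Ct values must be finite
and in (0, 45]; missing reactions are rejected by default, and
`drop_incomplete()` removes whole samples that lack any gene so that the
complete-matrix methods apply (imputation would fabricate exactly the
variation being measured).

On this scale one cycle is one doubling at 100% efficiency, so all noise
models and all log-ratio statistics operate in log2 units.

## Amplification efficiency and relative quantities

A standard curve regresses mean Ct on log10 relative template
concentration over a serial dilution (at least three points). The
efficiency in percent is `(10^(-1/slope) - 1) * 100`: a slope of
-1/log10(2) = -3.3219 cycles per decade is perfect doubling. Fits with
non-negative slope are returned but flagged, since they cannot come from a
working assay. The default efficiency everywhere else is exactly 2.0 (the
`Q = 2^dCt` convention); per-gene fitted efficiencies can override it.

Relative quantities anchor each gene at its own minimum Ct:
`x(g, s) = E_g^(minCt_g - Ct(g, s))`, so the most abundant sample scores 1
and all quantities lie in (0, 1]. The anchor is a per-gene constant and
cancels in every downstream ratio statistic; it only fixes the scale of
normalization factors.

## The four stability statistics

**Comparative delta-Ct.** For genes i and k, `S(i, k)` is the sample
standard deviation (n-1 denominator throughout the package) of
`Ct_i - Ct_k` across samples; a gene's stability value is the mean of
`S(i, k)` over its partners. Sample-loading shifts add the same constant
to both genes of a pair and cancel exactly. With all efficiencies equal to
2, these values are *identical* to first-iteration geNorm M values —
log2 ratios of relative quantities reduce to Ct differences — and the test
suite asserts that identity to 1e-10 on random tables.

**geNorm.** M is the mean SD of a gene's log2 expression ratios to every
other candidate. The stepwise procedure recomputes M on the remaining
panel and removes the highest-M gene until two remain; those two are
reported as the tied most-stable pair (their mutual M values are equal by
construction). Rankings use competition ranking — the final pair both get
rank 1 and the next gene rank 3 — because tied ranks must aggregate
consistently downstream; fractional ranks would silently shift every
average. An availability screen flags genes with full-panel M at or above
1.5, the conventional usability bound. Normalization factors `NF_n` are
per-sample geometric means of the n best genes' quantities, and the
pairwise variation `V(n, n+1)` is the SD over samples of
`log2(NF_n / NF_{n+1})`. The optimal panel size is the smallest n with
`V(n, n+1)` strictly below the cutoff, 0.15 by convention; the cutoff is a
guideline, not a hard rule, and is exposed as a parameter (screens with
higher overall variability commonly relax it to 0.2). If no V clears the
cutoff the full panel is returned with a warning flag rather than a
fabricated decision. A tie at the maximal M during exclusion is broken
toward the first-listed gene, deterministically and with a warning; exact
ties have measure zero on real data but arise in constructed fixtures.

**NormFinder-style decomposition.** Log2 expression `y(i, g, j)` (gene i,
group g, sample j) is modeled as gene level + sample loading + group
effect + noise. Per-sample centering (subtracting each sample's mean over
the k genes) removes loading exactly, but distorts variances: each
centered gene keeps only `(k-2)/k` of its own variance plus a `1/k^2`
share of every panel member's. The intra-group variance estimator inverts
that distortion:

    sigma2(i, g) = max(0, (k / (k - 2)) * (s2(i, g) - s2bar(g) / (k - 1)))

with `s2(i, g)` the sample variance of centered values and `s2bar(g)` its
mean over genes. It is unbiased by construction (for equal true variances,
`E[s2] = sigma2 (k - 1)/k`, and the estimator's expectation returns
`sigma2` exactly); the suite verifies calibration by Monte Carlo at 1000
replicates of n = 200, within 5% per gene, and negative estimates are
clamped to zero with the clamped fraction reported. Group deviations
`d(i, g)` (group means of centered data, centered across groups per gene)
are shrunk toward zero by an empirical-Bayes factor
`gamma2 / (gamma2 + sigma2(i, g)/n_g)`, where
`gamma2 = max(0, var(d) - mean(sigma2/n_g))` estimates how much of the
observed deviation spread exceeds sampling noise; `var(d)` is the sample
variance over all (gene, group) cells. The stability value is
`rho(i) = mean over groups of [ |d_shrunk(i, g)| + sqrt(sigma2(i, g)/n_g) ]`,
and with a single group simply `sqrt(sigma2(i))`. Groups are unweighted
(the emulated design is balanced). No numerical parity with the original
NormFinder binary is claimed — that tool's constants are not published to
reproduction precision — and acceptance for this module is property-based:
unbiasedness, loading/level invariance, and ordering recovery.

**BestKeeper.** Pure descriptives on raw Ct: per-gene dispersion about the
mean, coefficient of variation, and Pearson correlation with the
BestKeeper index (per-sample geometric mean of Ct over the panel), ranked
by dispersion. The default dispersion is the mean absolute deviation, the
convention of the original tool family; a flag switches to the sample SD
since screens differ in which they report. BestKeeper is deliberately
*not* loading-invariant — a per-sample shift moves every raw Ct — and the
suite asserts this as a documented limitation rather than hiding it: its
ranks answer "which gene's raw Ct wanders least", not "which gene is
stable after normalization".

## Aggregation across methods and conditions

RefFinder-style aggregation takes the four methods' competition ranks per
gene and combines them by unweighted geometric mean; genes are ordered
ascending in that value. Equal weights are the only mode: the published
aggregate values we checked are all consistent with a plain geometric
mean, and any nontrivial weighting would need evidence no screen provides.
The geometric mean is bounded by the minimum and maximum method rank, with
equality only under unanimity.

Across experimental conditions the package averages each method's
per-condition ranks arithmetically and reports them at two decimals with
round-half-up (matching how such tables are conventionally printed; the
full-precision values are kept alongside). The exclusion-sensitivity
reanalysis recomputes the averages with chosen conditions dropped and
reports each gene's rank shift — the operation behind "how much of this
gene's instability is between populations rather than within them".

The bundled `study_ranks()` / `study_ct_summary()` / `study_v_series()`
tables carry the printed per-condition ranks, Ct extremes and V values of
a published five-gene screen in the rice white-tip nematode, as inputs for
exactly this rank arithmetic; the screen's raw Ct data was never deposited
in a public archive. One V entry is censored: the source prints only the
decision-relevant V for one condition and states that all its V values
exceeded 0.15, so the n = 2 entry is stored as 0.200, meaning "not below
the 0.2 cutoff" under the strict-inequality rule, and flagged in the file.

## The synthetic generator

`generate_ct_table()` draws from the additive model on the Ct scale:

    Ct(i, s, rep) = mu_i + delta(i, group(s)) + L(s) + eps(i, s) + tau(i, s, rep)

with loading `L ~ N(0, sigma_L^2)` shared by all genes of a sample,
per-gene instability `eps ~ N(0, sigma_i^2)`, technical noise
`tau ~ N(0, sigma_tau^2)` per replicate, and fixed group effects `delta`.
This is exactly the assumption set under which the ratio-based statistics
are valid, which is the point: it yields data where ground truth is known
(`ground_truth_order()` sorts genes by `sigma_i^2 + Var_g(delta(i, .))`)
so every stage of the pipeline is testable without any download. Draw
order is fixed (samples group by group; per sample one loading draw, then
per gene one instability draw and r technical draws) so a seed pins the
table byte-for-byte, and the session RNG state is restored afterwards.

The default spec emulates a five-candidate nematode screen: 12 samples in
four groups of three with three technical replicates; base Ct levels 12.89
(18S rRNA), 21.12 (actin), 24.85 (GAPDH), 25.53 (UBC) and 25.68
(alpha-tubulin) cycles — the observed panel means of the emulated study;
instability SDs of 0.45, 0.30, 0.25, 0.15 and 0.35 cycles respectively,
chosen once so the implied stability order matches that study's
mixed-population ranking (UBC most stable, 18S least); a per-group shift
on 18S of (-0.5, 0.2, 0.5, -0.2) cycles emulating ribosomal copy-number
differences between populations; loading SD 0.5 and technical SD 0.1
cycles, typical magnitudes for careful pipetting on a single plate.

What the generator does *not* emulate: non-Gaussian dropout of late
reactions, efficiency drift across cycles, inhibition, inter-plate
effects, or a gene that is stable within populations but unstable between
them combined with low within-population noise (the default 18S is noisy
in both senses — a simplification). Passing tests on this model therefore
demonstrate correctness of the statistics under their own assumptions,
not robustness of reference-gene screening to assay pathology.

## What is statistically resolvable at screen scale

A point the implementation surfaced and the tests encode: with 12 samples,
a gene with instability SD 0.10 cycles cannot be reliably distinguished
from one at 0.15 — the variance ratio is 2.25 on ~11 degrees of freedom,
a ~10% flip probability for that pair alone before the panel's shared
variance floor is added (per-sample centering and shared delta-Ct partners
hand every gene a slice of its neighbours' noise). Simulation at those
conditions identifies the true best gene only ~53-87% of the time
depending on the method, while the clearly separated *worst* gene is
flagged in well over 90% of runs. The recovery tests therefore assert
resolvable claims: the least stable gene is identified, the best gene
lands in the top two, and top-rank identification beats chance
several-fold. Full-ordering recovery is asserted where it is actually
achievable: five genes with SDs 0.1-0.9 cycles in even steps, four groups
of 20 samples, where the NormFinder decomposition recovers the complete
designed ordering in ≈95% of 200 seeded runs. Practically this is the
same caution a bench scientist needs: a screen of a dozen samples ranks
the extremes trustworthily, but adjacent ranks near the top are within
noise.

## Numerical conventions, collected

- Sample SDs and variances use the n-1 denominator everywhere.
- All logs are base 2; Ct input to NormFinder enters as -Ct (per-gene
  constants are immaterial after centering).
- Competition ranking for all ties (1, 1, 3, ...).
- geNorm exclusion ties break toward the first-listed gene, with warning.
- Negative variance estimates clamp to zero; the clamped fraction is
  recorded on the result object.
- Quartiles in Ct summaries are Tukey hinges (the inclusive,
  median-in-both-halves convention).
- Degenerate one-way ANOVA (zero total variance) returns F = 0, p = 1
  with a warning instead of erroring, so noiseless fixtures pass through;
  ANOVA grouping is a parameter because screens differ in whether
  replicates or conditions form the groups.
- Report tables print stability values at three decimals and average
  ranks at two, round-half-up; computation keeps full precision.
- The pipeline is deterministic: rerunning on the same input and
  configuration reproduces output files byte for byte.

## Problem sizes used by the checks

The Monte-Carlo calibration of the variance estimator uses 1000 replicates
of 5 genes x 200 samples; the ordering-recovery study uses 200 seeds of
5 genes x 80 samples; the delta-Ct/geNorm identity is checked on 100
random tables; end-to-end pipeline checks run on the 12-sample default
spec. These sizes make every property estimate stable to well under its
asserted margin while keeping a full run of the suite in tens of seconds.

## Known limitations

- BestKeeper ranks depend on raw-Ct dispersion and are sensitive to
  loading; they are included because aggregate rankings conventionally
  require all four methods, not because the statistic is recommended
  alone.
- The NormFinder-style module follows the estimator stated above, not the
  original binary's internals; rank-level agreement is the supported
  claim.
- geNorm's tied final pair means the method cannot name a unique best
  gene; aggregation handles this via competition ranks.
- No instrument-native file import, melting-curve processing, inter-run
  calibration, or target-gene normalization: the package starts at a Ct
  table and ends at stability rankings and panel-size decisions.
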