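---
title: "Methods: two-sample Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. A SNP $j$ qualifies as an instrument under three
assumptions: it is associated with the exposure (relevance), it shares no
confounder with the outcome (independence), and it affects the outcome
only through the exposure (exclusion restriction). In the two-sample
design the SNP–exposure associations $(\hat\gamma_j, \sigma_{Xj})$ and
SNP–outcome associations $(\hat\Gamma_j, \sigma_{Yj})$ come from separate,
non-overlapping GWAS; for binary traits both are on the log-odds scale.

Each instrument yields a Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order
(delta-method) standard error $\sigma_{Yj} / |\hat\gamma_j|$, which
ignores the exposure-side sampling error — the standard convention for
strong instruments, and the one under which published confidence
intervals in this literature are constructed. The primary estimator is
the inverse-variance weighted (IVW) mean of the ratios with weights
$w_j = 1/\mathrm{se}(\hat\theta_j)^2$. Cochran's
$Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2$ measures
heterogeneity on $k-1$ degrees of freedom; when the heterogeneity test
rejects, the multiplicative random-effects (MRE) model inflates the IVW
standard error by $\max(1, \sqrt{Q/(k-1)})$. MR-Egger regresses
$\hat\Gamma_j$ on $\hat\gamma_j$ with an unconstrained intercept
(instruments re-oriented to positive exposure effects); the intercept
estimates the average directional pleiotropy and the slope is a
pleiotropy-robust causal estimate. The weighted median interpolates the
ordered ratios at 50% cumulative weight and is consistent while valid
instruments carry at least half of the weight. MR-PRESSO detects
pleiotropic outliers from the residual sum of squares around
leave-one-out IVW predictions, with a simulated null.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| `p_max` | $5\times10^{-8}$ | genome-wide significance for relevance |
| `maf_min` | 0.01 | variants below 1% MAF give unstable case-control estimates |
| `info_min` | 0.9 | conventional imputation-quality floor |
| `palindromic_eaf_window` | 0.08 | drop A/T and C/G SNPs with EAF in [0.42, 0.58]: frequency cannot resolve strand near 0.5 |
| `r2_min` | 0.8 (strict `>`) | conventional LD-proxy threshold |
| IVW heterogeneity trigger | $p_Q < 0.05$ | switches `auto` to the MRE model |
| `n_boot` | 1000 | weighted-median bootstrap SE resolution |
| `n_sim` | 1000 | MR-PRESSO p-value resolution (add-one floor $1/(n_{sim}+1)$) |
| power `alpha` | 0.05 two-sided | reporting convention |

All stochastic routines take an explicit `seed` and restore the caller's
RNG state; identical seeds give bit-identical results.

## Design choices

Several points are left open by common practice and were fixed as
follows.

* **Palindromic SNPs.** Allele labels cannot identify strand for A/T and
  C/G variants, so orientation uses allele frequency, and only when both
  EAFs are clearly away from 0.5 (window above). A palindromic SNP with a
  missing EAF is dropped; a non-palindromic SNP with missing EAF is kept,
  since its alleles suffice.
* **Filter attribution.** Retention is a conjunction of all filters (so
  the retained set is order-independent); the recorded removal reason is
  the first failing filter in the order exclusion list, MAF,
  significance, INFO.
* **Variance explained.** $R^2 = \sum_j 2 p_j (1-p_j) \hat\gamma_j^2$
  with a unit-variance phenotype, the standard summary-statistic
  approximation for the overall F-statistic
  $F = \frac{N-k-1}{k}\,\frac{R^2}{1-R^2}$. It is isolated in
  `r2_from_summary()` so an alternative can be swapped in.
* **MRE floor.** The random-effects inflation never shrinks below the
  fixed-effect SE ($\max(1,\cdot)$), preventing anti-conservative
  inference when $Q < k-1$.
* **P-value references.** IVW and weighted-median p-values use the
  normal distribution; MR-Egger uses $t_{k-2}$ because it estimates a
  residual scale. Confidence intervals use the 1.96 multiplier to match
  reporting conventions.
* **Weighted median variant.** The simple inverse-variance-weighted
  variant (not the penalized one), with a parametric-bootstrap SE.
* **MR-PRESSO statistic.** Residuals are unweighted squared deviations
  of the outcome effects from leave-one-out IVW predictions; sampling
  variability enters through the simulated draws, making the null
  self-calibrating. Empirical p-values use the add-one estimator. The
  outlier test Bonferroni-adjusts per-SNP p-values by $k$ and flags at
  0.05. The distortion test removes random subsets of *non-outlier*
  instruments of the same size as the outlier set; drawing from all
  instruments would reproduce the outlier's own displacement in a
  fraction of draws and dilute the test.
* **Driving instruments.** Leave-one-out flags a SNP when its removal
  flips the sign of the pooled estimate or moves its p-value across
  0.05 — an explicit rule replacing the visual forest-plot inspection
  typically used.
* **Bonferroni reporting.** The adjusted threshold is reported rounded
  to 3 decimals (0.05/3 prints as 0.017) while comparisons use the
  unrounded value.
* **Proxy substitution.** The proxy's outcome record is analysed under
  the requested instrument's identity. No LD phase information is
  consumed, so the proxy's alleles must still reconcile with the
  exposure record during harmonization; irreconcilable pairs are dropped
  and logged.

## The synthetic-data generator

`simulate_mr_summary()` draws, per SNP: a minor allele frequency
$\mathrm{maf}_j \sim U(0.1, 0.5)$; a true exposure effect
$\gamma_j \sim N(0, 0.1^2)$; the large-sample case-control SE
$\sigma_{Xj} = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,N_X K_X(1-K_X))^{-1/2}$;
an observed $\hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2)$; a direct
(pleiotropic) outcome effect $\alpha_j$ for a seeded fraction
`prop_invalid` of SNPs; and an observed
$\hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$.

The defaults emulate the study scale this package was built around: an
exposure GWAS of 217,955 samples with case fraction 16,761/217,955 (a
national-biobank sleep-apnea study) and an outcome GWAS of 659,316
samples with case fraction 62,892/659,316 (a European type-2-diabetes
consortium). With these, the implied exposure SEs (about 0.012 at
EAF 0.18) match the published instrument table's SEs (0.011–0.016), and
`gamma_scale = 0.1` matches its effect sizes (0.073–0.104), so the
generator reproduces the first two moments of the real instrument table.
Tables are reported on the exposure-increasing allele, the convention of
published instrument tables, and pleiotropic effects are assigned on that
oriented scale so `pleiotropy_mean > 0` is genuinely directional.

What the generator does **not** emulate: LD between variants (the real
instruments are independent loci, so none is simulated), selection of
instruments by a discovery scan in the same sample (winner's curse),
minor-allele-frequency–effect-size coupling, INFO scores, and
population-stratification artefacts. Passing calibration tests on this
generator therefore demonstrates correctness of the estimators under the
stated sampling model, not robustness to every failure mode of real
summary statistics.

## Numerical behaviour and known limitations

* **Weak-instrument attenuation.** Because exposure effects are drawn
  from $N(0, 0.1^2)$, some simulated instruments are weak, and the IVW
  estimate inherits the classical regression-dilution attenuation of
  order $\sigma_X^2/\mathrm{gamma\_scale}^2$ (under 2% here), plus a
  small SE understatement because the first-order Wald SE omits the
  $\theta^2\sigma_{Xj}^2$ dispersion term. At the default outcome
  precision this leaves the empirical 95% CI coverage at
  $\theta = 0.2$ slightly below nominal (the acceptance suite measures
  it, around 0.92–0.93) while the type-I error at $\theta = 0$ is
  nominal. Filtering instruments by significance does not remove the
  effect (winner's curse preserves the dilution). This is a property of
  the estimator conventions, not of the implementation; the tests
  document it rather than hide it.
* **Egger intercept scale.** With a fraction $\pi$ of invalid
  instruments carrying mean direct effect $\mu$, the Egger intercept is
  consistent for the weight-averaged direct effect over *all*
  instruments, approximately $\pi\mu$ — not $\mu$. Interpretation of
  the intercept magnitude must account for the invalid fraction.
* **MR-PRESSO at small k.** The simulated null re-estimates the
  leave-one-out slopes inside every replicate; at small instrument
  counts (around k = 10) this makes the global test conservative, while
  at k = 20 it is well calibrated. The package's operating
  characteristics are therefore quoted at k = 20.
* **Degenerate inputs.** One instrument: IVW degenerates to the Wald
  ratio, Q is not applicable; two: leave-one-out returns single-SNP Wald
  ratios; fewer than three: Egger, weighted median and MR-PRESSO refuse.
  Zero retained instruments is fatal for an outcome but not for a
  multi-outcome run.
* **Ties and tie-breaks.** Proxy candidates tied on r² resolve to the
  lexicographically smallest rsID (deterministic, seed-free); the
  weighted-median interpolation uses ordered cumulative-midpoint ties.

## Problem sizes used by the test suite

The calibration suites run 1000 replicates at J = 50 instruments for IVW
type-I error, mean recovery and coverage; 300 replicates for the
pleiotropy (Egger/weighted-median) suite; 500 replicates at k = 20 and
`n_sim = 300` for the MR-PRESSO null; and 100 seeded replicates at
k = 20, `n_sim = 1000` for planted-outlier detection. These sizes give
binomial standard errors of about 0.7–1% on the estimated rates and run
in a few minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
cand <- osa_instruments()
sel <- select_instruments(cand, exclude = "rs9937053")
sim <- simulate_mr_summary(n_snps = 20, theta = 0.2, seed = 7)
h <- harmonize(sim$exposure, sim$outcome)
mr_ivw(h)$estimate
mr_egger(h)$slope
mr_weighted_median(h, n_boot = 1000, seed = 7)
mr_presso(h, n_sim = 1000, seed = 7)$global_p
```

The pipeline front end `run_mr_pipeline()` chains the same calls for
several outcomes, applies the Bonferroni rule across them, and writes
every table plus a deterministic JSON index.
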