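---
title: "Modelling triglyceride responsiveness to EPA and DHA with a genetic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling triglyceride responsiveness to EPA and DHA with a genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n3grs)
```

## The problem and the design

Supplementation with marine omega-3 fatty acids lowers plasma
triglycerides (TG) on average, yet individual responses range from
strong reductions to paradoxical increases. `n3grs` implements a
pipeline for asking whether a fixed multi-SNP genetic risk score,
built in a discovery cohort, predicts that heterogeneity in an
independent crossover trial in which every participant receives EPA,
DHA and a control oil in randomised sequence.

The pipeline has four scientific stages, each exposed as ordinary
functions:

1. **Genotype QC** — effect-allele frequencies, a 1-df Pearson
   chi-squared test of Hardy–Weinberg equilibrium (HWE) per SNP with
   exclusion of violators, and 2×2 allele-count chi-squared
   comparisons of frequencies between cohorts or subgroups.
2. **Scoring** — the signed unit-weight rare-allele count
   `sum_j d_j x_ij`, with `d_j = +1` when the discovery odds ratio
   exceeded 1 and `-1` when it was below 1.
3. **Responder classification** — the crossover TG change
   `delta = TG_post-treatment - TG_post-control` is compared against an
   intra-individual variability window of half-width `w`, giving the
   ordered classes R < NR < AR.
4. **Association** — a proportional-odds model of class on score,
   adjusted for age, sex and BMI; a binary AR-vs-R model with NR
   excluded; predicted-probability curves with confidence bands;
   subgroup allele-frequency scans.

## Model and assumptions

The ordinal model is the cumulative-logit proportional-odds model

$$\mathrm{logit}\, P(Y_i \le k \mid x_i) = \zeta_k - (\beta\,
\mathrm{GRS}_i + \gamma' z_i), \qquad k \in \{R,\ NR\},$$

with a single slope per predictor across both cutpoints. With the
ordering R < NR < AR, a positive $\beta$ (odds ratio
$e^\beta > 1$) means each additional signed risk allele shifts odds
toward the adverse end. This orientation is a package convention; the
mirrored parameterisation is recovered exactly by reversing the factor
order (a property the test suite asserts).

Assumptions worth keeping in mind:

* **Proportionality** — one slope acts on both cumulative logits. No
  formal proportional-odds test is run by default; with a class split
  as small as a typical AR group (~10% of a hundred-odd participants)
  such tests have little power and mostly add noise. Fitting the
  binary AR-vs-R model alongside is the pragmatic robustness check.
* **Fixed panel orientation** — effect alleles and direction signs
  come from the panel definition, never re-estimated in the analysis
  cohort. Re-estimating directions from the same cohort that supplies
  the outcome would leak outcome information into the score.
* **Unit weights** — the score counts alleles with ±1 weights; no
  effect-size weighting or standardisation is offered, matching the
  score the pipeline exists to evaluate.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `hwe_alpha` | 0.05 | — | per-SNP 1-df chi-squared level; no multiplicity correction, since the filter is a QC screen, not an inference |
| `rare_maf_threshold` | 0.05 | frequency | *inclusive* flag (`maf <= 0.05`): a SNP printed at exactly 5% is counted as rare |
| `window` | 0.25 | mmol/l | half-width of the NR window; the cohort value behind the method. `"estimate"` derives it from off-treatment replicates |
| `missing_policy` | `"skip"` | — | missing SNP contributes 0 to the score and is counted; `strict` errors; `mean_impute` substitutes `2·MAF` |
| `max_missing_frac` | 0.2 | fraction | participants missing more than this share of panel SNPs are flagged, not silently dropped |

Boundary conventions are deliberate and tested: a TG change equal to
the window (`|delta| = w`) is *inside* the window, hence NR; an odds
ratio of exactly 1 has no direction and `direction_from_or(1)` is an
error rather than a silent 0; a monomorphic SNP is reported as
chi-squared 0, p 1 with a flag, not an error.

## The window estimator

`estimate_window()` computes each participant's sample SD over their
repeated off-treatment TG measurements and averages over the cohort.
With only $k = 4$ replicates the sample SD is biased low:
$E[s] = c_4(k)\,\sigma$ with $c_4(4) \approx 0.921$. The default
therefore divides the cohort mean by $c_4(k)$, making the window an
unbiased estimate of the intra-individual SD — so a generator with
true SD 0.25 mmol/l is recovered as 0.25, not 0.23.
`correct_bias = FALSE` gives the raw mean of sample SDs for users who
want the uncorrected convention.

## Numerical choices in the ordinal fitter

The proportional-odds likelihood is maximised by Newton iterations
with the analytic gradient and a central finite-difference Hessian of
that gradient, with step-halving and a strict-ordering guard on the
cutpoints. Convergence requires a gradient max-norm below `1e-6`
(relative log-likelihood stagnation below `1e-8` is accepted only when
step-halving can no longer improve the fit). Starting values are the
marginal cumulative logits with zero slopes. Estimates diverging past
|30| on the logit scale abort with a separation diagnostic; a
singular information matrix (constant or collinear predictor) is an
explicit error, never `NA` output. The test suite cross-checks
coefficients, cutpoints, log-likelihood and standard errors against an
independent proportional-odds implementation, and checks the exact
two-category equivalence with binary logistic regression.

One property worth recording: the familiar logistic-regression
identity "average fitted probability = observed frequency" holds
exactly only for the binary model. For proportional odds the cutpoint
score equations weight observations by the logistic density, so
averaged fitted category probabilities differ from observed
frequencies by a small amount (order 1e-4 in cohorts of a few
hundred). The suite therefore asserts the exact score equations
(gradient ~ 0 at the optimum) and the binary-case frequency match,
not a frequency match for the three-class model.

**Confidence bands.** For classes that are a single inverse-logit of a
linear predictor (the extreme ordinal classes, both binary classes)
the 95% band is the delta method on the linear predictor transformed
through the link, so it respects [0, 1] by construction. The middle
(NR) class is a difference of two cumulative probabilities with no
single linear predictor; its band uses the delta method on the
probability scale, clipped to [0, 1]. A parametric-simulation band
(coefficient draws from the asymptotic normal) is available for all
classes and agrees with the delta bands to a few percent in the tested
regimes.

## What the synthetic-data generator emulates

`sim_config()` defaults *are* the study conditions the package
targets: 122 participants; the 31-SNP panel with its published
replication-cohort allele frequencies; post-control TG marginals
1.43 ± 0.71 mmol/l; mean fractional reductions 13.3% (EPA) and 18.9%
(DHA); four off-treatment replicates with intra-individual SD
0.25 mmol/l; a score effect of log(1.2) per unit on the cumulative
logit.

Choices the source material leaves open, fixed once here:

* **Direction signs.** The discovery cohort's per-SNP odds-ratio
  directions were never published, so the bundled panel sets every
  direction to +1 (the score reduces to a total rare-allele count).
  All signed behaviour is exercised in tests with mixed-sign panels.
  Likewise the bundled effect/other allele symbols (A/G) are
  simulation placeholders, not real allele calls.
* **Cutpoints.** Only the adverse-responder counts (about 10% of the
  cohort) are known; the R/NR split is not. The preset uses marginal
  cumulative logits `qlogis(c(0.45, 0.90))` — 45% R, 45% NR, 10% AR at
  the mean score — as a realistic split for a cohort whose mean TG
  drops by 13–19%.
* **Centring.** The latent predictor is
  `beta * (GRS - mean(GRS)) + centred covariate terms`, so the
  configured cutpoints are marginal quantities and class frequencies
  do not drift with the panel's allele-frequency total. This is a
  reparameterisation, not a different model.
* **Label-first generation.** The class is drawn from the latent
  model first and the TG change is then drawn from a truncated normal
  restricted to that class's window interval (class-conditional means
  −0.5 / 0 / +0.5 mmol/l, SD 0.2; the R mean additionally tracks the
  treatment's fractional reduction). Classification of the simulated
  change therefore reproduces the drawn class *exactly*, which is what
  makes the round-trip test sharp. A `delta_first` scheme draws the
  change continuously and derives labels, for sensitivity checks; it
  has no independent truth label by construction.
* **Positivity.** Post-control TG is truncated below `window + 0.15`
  (so every class interval is non-empty for every participant), with
  the normal location shifted so the truncated marginal keeps the
  configured mean.

Features of real data the generator deliberately omits: linkage
disequilibrium between panel SNPs (the score is additive, so
independence does not distort score-level behaviour, but SNP-level
subgroup scans are cleaner than reality), population structure,
genotyping error, within-person correlation between the EPA and DHA
classes (drawn independently given the score), and carry-over effects
between crossover phases. Passing tests on simulated data therefore
validate the *statistical machinery* under the assumed model, not the
biological claim on any real cohort.

## Problem sizes in the test suite

The suite's Monte-Carlo checks use sizes chosen to make the relevant
standard errors decisive: parameter recovery over 200 replicates at
n = 2000 (ordinal, true OR 1.2) and n = 1000 (binary, true OR 2.3)
with a two-Monte-Carlo-SE band; type-I error of the HWE and Wald tests
over 2000 replicates at the study's genotype scale (n = 122) and
n = 500 respectively; window recovery at n = 500 within ±0.02 mmol/l;
closed-form 2×2 oracles enumerated over small tables; the HWE
chi-squared/z-statistic identity enumerated over all genotype triples
up to n = 30.

## Known limitations

* Only biallelic SNPs; no imputation, phasing or multi-allelic
  support. The VCF reader refuses allele mismatches rather than
  attempting strand flips.
* Published between-cohort chi-squared values for the bundled panel
  are carried as data but are not exactly recomputable from the
  rounded printed frequencies (the discovery denominators are not
  public), so they serve as reference columns, not oracles.
* Wald inference throughout; with very small class counts (AR groups
  of ~10) profile-likelihood or exact methods would be preferable, and
  the reported p-values should be read accordingly.
* The window constant 0.25 mmol/l is a cohort property, not a
  biological constant; cohorts with different TG variability should
  re-estimate it (`window = "estimate"`).
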