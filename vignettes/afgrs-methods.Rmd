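---
title: "Methods: weighted genetic risk scoring for atrial fibrillation"
author: "afgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted genetic risk scoring for atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afgrs)
```

## The model

Atrial fibrillation (AF) has a substantial heritable component, and a
handful of common variants — most prominently at the chromosome 4q25 locus
near *PITX2* — carry reproducible risk. `afgrs` implements a weighted
allele-counting genetic risk score (GRS) over a 12-SNP panel spanning 9
genes. For participant $j$ with dosage $g_{ij} \in \{0,1,2\}$ of the
*modeled* allele at SNP $i$,

$$ s_j = \sum_{i} w_i \, g_{ij}, $$

where the weights $w_i$ are log-odds-scale effect sizes taken from the
panel. Dosage always counts the modeled allele, not the minor allele:
protective alleles keep their own count and carry a negative weight (4 of
the 12 weights are negative). This sign convention makes the score linear
in dosage with fixed, interpretable bounds: the extreme genotypes give
$2\sum_{w_i<0} w_i = -1.42$ and $2\sum_{w_i>0} w_i = +3.46$, and under
Hardy–Weinberg genotype frequencies the population mean is
$2\sum_i f_i w_i \approx 0.454$.

The built-in `afPanel("af9")` is the one-SNP-per-gene reduction that keeps
rs2200733 for *PITX2* — the standard remedy for confounding by linkage
disequilibrium (LD) among co-located panel SNPs. Its weights are carried
over unchanged: re-estimating them would require a training cohort, and
the published 9-SNP analysis gives no re-fitted weights, so reuse is the
only defensible default.

## Missing genotypes and stratification

Missing dosages are replaced by the mean of the *observed* dosages at the
same marker (additive coding). This preserves per-marker observed means
exactly and guarantees a finite score for every participant. The
frequency-based fallback $2f_i$ is used only for a marker with no observed
genotypes at all, and only when a panel is supplied — otherwise that is an
error, because silently inventing a column is worse than failing.

Quintile and tertile groups are cut at type-7 (linearly interpolated)
sample quantiles. Membership uses closed upper intervals — a score exactly
equal to a cut point belongs to the lower group — matching the convention
of published quintile range footnotes (Q1 $\le$ first cut, Q2 above it and
$\le$ the second, ...). With tied scores this rule produces slightly
unequal group sizes; that is correct behaviour, not a defect. Whether the
original analysis used interpolated or empirical quantiles is not
documented; cut points are data-dependent either way, and on realistic
cohorts the two differ by less than the Monte-Carlo noise of the cohort
draw.

## The synthetic cohort generator

No participant-level data accompany the original study, so the package
ships a generator that emulates the cohort's structure and makes every
downstream stage testable:

* **Genotypes** are Binomial(2, $f_i$) per SNP (Hardy–Weinberg, random
  mating). One SNP pair — by default the *PITX2* pair
  rs2200733/rs10033464, whose risk alleles are negatively associated in
  real cohorts — is drawn from a two-SNP haplotype distribution with a
  signed haplotype covariance $D$, which preserves both marginal
  frequencies exactly. Only the sign of the real-world $D$ is documented
  (via an association p-value), not its magnitude, so $D$ is an explicit
  free parameter; the default is half the most negative admissible value
  for the pair's frequencies ($D = -0.0065$).
* **Covariates** are drawn independently (published baseline tables report
  margins only, so a copula would be invented structure): age
  truncated-normal with a 40-year inclusion floor, BMI truncated-normal,
  binary covariates Bernoulli at cohort prevalences (38% male, 77%
  hypertension, 22% diabetes, ...). For the truncated normals the
  pre-truncation location is solved numerically so the *post*-truncation
  mean hits the configured target (66.2 years, 29.6 kg/m²); without that
  shift truncation at 40 would inflate mean age by ~0.4 years.
* **Outcomes** come in two modes. `quintile_rates` assigns each
  participant the event probability of their GRS quintile — the design
  used for power analysis. `logistic` draws
  Bernoulli$(\mathrm{expit}(\beta_0 + \beta_g z_j + x_j^\top \beta_c))$
  with $z_j$ the GRS standardized by its sample SD; $\beta_0$ is
  auto-calibrated by bisection so the expected marginal event rate matches
  a target (default 85/904 $\approx$ 9.4%). Default covariate effects are
  modest, clinically plausible log-odds (see `defaultOutcomeBetas()`).

What the generator does *not* emulate: correlated covariates, population
structure and ancestry admixture, genotyping error, haplotype blocks
beyond the single configured pair, and time-to-event structure. Passing
tests therefore demonstrate the correctness of the statistical machinery
under the stated generative model, not the reproduction of any
cohort-specific estimate: quantities such as the observed score range
(−0.84 to 1.78), quintile cut points (0.14/0.33/0.50/0.77) or the
C-statistic pair 0.687/0.719 depend on the unreleased cohort and are
covered instead by parameter-recovery properties (known simulation truth
recovered within Monte-Carlo error, 95% CI coverage between 93% and 97%).

## Association analyses

* **Baseline tables** compare each covariate between AF and no-AF groups:
  Welch's unequal-variance t-test for quantitative traits and the
  Yates-corrected chi-squared test for binary ones. These two choices are
  not arbitrary: recomputing published baseline p-values from the printed
  (mean, SD, n) summaries and counts reproduces them at the printed
  rounding under Welch + Yates, and not under the pooled t or uncorrected
  chi-squared. `welchFromSummary()` deliberately accepts summary
  statistics so published tables can be re-tested without raw data.
* **GRS models** are maximum-likelihood logistic regressions with four
  predictor codings — per-SD continuous, quintile dummies (lowest quintile
  as reference), ordinal quintile index, tertile dummies — unadjusted or
  adjusted for age, sex, smoking, BMI, diabetes, hypertension, prior MI
  and heart failure. Both quintile codings are provided because "GRS as a
  quantitative variable using quintile categories" admits either reading.
  CIs are 95% Wald intervals on the log scale (the standard presentation
  for OR (95% CI) tables); profile-likelihood intervals would differ in
  the third digit at these sample sizes.
* **Separation** (perfect prediction) raises an explicit error in model
  fits rather than returning silently huge coefficients. In the per-SNP
  scan, a single unstable marker is flagged (`flag = "unstable"`, NA
  estimates) instead of aborting the other 11 fits.
* **C-statistics** of nested models (clinical covariates vs covariates +
  GRS) are compared with the paired DeLong test. The source analyses
  report a p-value for the C-statistic gain without naming a method;
  DeLong is the field default for paired ROC curves and is the assumption
  made here.

## Power engine

The prospective design is simulated directly: $n$ participants split
evenly over 5 quintiles (quintiles are equal-sized by construction in the
design, hence exactly $n/5$ each), event counts Binomial at rates
$\bar p + \delta(q-3)$ — defaults $\bar p = 8\%$, $\delta = 2$ percentage
points, i.e. 4/6/8/10/12%, simultaneously "2% per quintile", "half the
average in the lowest" and "1.5× the average in the highest" — and the
quintile–event association tested per replicate. The default test is the
Wald test on the ordinal quintile coefficient of a logistic fit (fitted on
the 5 aggregated binomial rows, which is the identical likelihood at a
fraction of the cost); a Cochran–Armitage-style trend test is selectable,
and both comfortably clear 90% power under the default design (≈92% at
2,000 replicates, Monte-Carlo SE 0.6 points, with 80 expected events per
1,000 participants). A replicate with zero events counts as a
non-rejection. Alpha is two-sided. Replicate counts: 2,000 by default
(the original computation's count is unreported); the binomial MC
standard error is always returned alongside the estimate.

## Numerical choices and problem sizes

Tests exercise the scoring engine against a brute-force per-cell oracle at
machine precision, verify HWE/LD marginals at $n$ = 20,000–50,000 where
closed forms exist, and run stochastic calibration checks (type-I error,
CI coverage, power monotonicity) at 150–2,000 replicates with fixed seeds
— sizes chosen so Monte-Carlo error bands (3 binomial SEs) are decisive
for the properties being checked. Intercept calibration brackets
$\beta_0 \in [-25, 25]$ and fails loudly if the target rate is
unreachable. Admissibility of the LD parameter is checked against the
exact haplotype-frequency bounds and reported with the bound when
violated.

## Limitations

The package validates methodology on synthetic cohorts; it does not ship,
and cannot reconstruct, the original participant data. VCF input matches
records by rsid and requires the modeled allele to equal REF or an ALT —
there is deliberately no strand inference or allele flipping, and no
genotype QC (call-rate or HWE filtering). Survival / time-to-event
modelling, ethnicity-specific re-weighting and multiple-testing correction
of the per-SNP scan are out of scope.
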