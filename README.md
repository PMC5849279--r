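# afgrs — weighted genetic risk scoring for atrial fibrillation

Atrial fibrillation (AF) is the most common pathological arrhythmia and a
major cause of embolic stroke, yet it is frequently subclinical. Common
variants — most prominently at 4q25 near *PITX2* — carry reproducible AF
risk, and a weighted genetic risk score (GRS) over a small SNP panel can
stratify which symptomatic patients are most likely to manifest AF during
a short ambulatory monitoring window. `afgrs` is for biostatisticians and
genetic epidemiologists who want that analysis as a tested, reusable R
pipeline.

The score for participant $j$ is the weighted allele count

$$ s_j = \sum_{i=1}^{12} w_i\, g_{ij}, $$

with $g_{ij} \in \{0,1,2\}$ the dosage of the *modeled* allele at SNP $i$
and $w_i$ its log-odds weight (negative for protective modeled alleles).
The package provides:

* the canonical 12-SNP panel (`afPanel("af12")`) and its one-SNP-per-gene
  9-SNP reduction (`afPanel("af9")`, keeping rs2200733 for *PITX2*),
  plus readers for panel files, dosage CSVs and VCF;
* mean-dosage imputation of missing genotypes and quintile/tertile
  stratification with closed-upper interval membership;
* a synthetic cohort generator — Hardy–Weinberg genotypes with
  configurable negative LD for the *PITX2* pair, clinical covariates,
  and quintile-gradient or calibrated logistic outcome models;
* association analyses: Welch/Yates baseline tables (computable straight
  from published summary statistics), logistic GRS–AF models under per-SD,
  quintile, ordinal and tertile codings with Wald CIs, DeLong comparison
  of nested-model C-statistics, and a per-SNP scan;
* a Monte-Carlo power engine for the quintile-gradient design.

Classes are Bioconductor-style S4: `SnpPanel`, `AfCohort` (a
`SummarizedExperiment` with a `dosage` assay), `GrsVector`.

## Worked example

```r
library(afgrs)

cohort <- simulateCohort(simConfig(n = 904), seed = 11)
cohort
#> AfCohort: 904 participants x 12 SNPs
#>   missing dosages: 0 (0.00%)
#>   covariates: age, male, smoker, bmi, diabetes, hypertension, prior_mi, heart_failure
#>   AF events: 81 / 904

grs <- assignQuantiles(computeGrs(imputeMissing(cohort)), 5)
grs
#> GrsVector for 904 participants
#>   score: mean 0.466, SD 0.403, range [-0.600, 1.900]
#>   quintile cut points: 0.130, 0.340, 0.530, 0.800

fitGrsModel(cohort, grs, coding = "sd", adjusted = TRUE)
#> GRS-AF logistic association (sd coding, adjusted)
#>    term    or ci_lower ci_upper      p_value
#>  grs_sd 1.566  1.24798  1.96609 0.0001086221

runPower(powerDesign(), seed = 1)
#> Monte-Carlo power (ordinal_logistic_wald), 2000 replicates, n = 1000, alpha = 0.05
#>   quintile rates: 4%/6%/8%/10%/12%
#>   power = 0.923 (MC SE 0.0060)
#>   events: mean 80.0 (analytic expectation 80.0)
```

The simulated cohort had 81 AF events in 904 participants (a ~9% event
rate); its fitted adjusted odds ratio of 1.57 per SD of GRS reflects this
particular draw's sampling noise around the simulation truth of 1.43.
The quintile cut points fall where the population score distribution puts
them (mean ≈ 0.45 under Hardy–Weinberg at the panel frequencies). The
power run shows the quintile-gradient design — AF rate rising from 4% to
12% across GRS quintiles, 200 participants each — is detected at
two-sided alpha 0.05 in ~92% of replicate cohorts, with 80 events
expected per 1,000 participants.

Baseline-table statistics can be recomputed directly from published
summaries, without raw data:

```r
welchFromSummary(65.9, 11.8, 819, 68.5, 11.2, 85)$p.value  # age: 0.045
chisqFromCounts(297, 819, 44, 85)$p.value                  # male: 0.0072
```

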