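# vitdmr

Mendelian randomisation of vitamin D status and type 2 diabetes.

## What this package is for

Observational studies report that higher plasma 25-hydroxyvitamin D
(25(OH)D) is associated with lower risk of type 2 diabetes, but 25(OH)D
tracks latitude, season, adiposity and outdoor activity, so the association
may be confounded. `vitdmr` is for biostatisticians and genetic
epidemiologists who want to estimate the *causal* effect of 25(OH)D on
diabetes risk using genetic variants as instrumental variables, and to
compare it with the conventional observational estimate — as a complete,
reproducible pipeline that runs end to end on synthetic cohorts emulating a
large Chinese biobank (82,464 genotyped adults across a 20-46 degree
latitude range, a 13,069-person measured-exposure subset, ~6.7% diabetes).

The genetic toolkit covers the four established 25(OH)D instruments — two
synthesis SNPs (*DHCR7*-rs12785878, *CYP2R1*-rs10741657), one transport SNP
(*GC/DBP*-rs2282679), one catabolism SNP (*CYP24A1*-rs6013897) — with
Hardy-Weinberg checks, area-stratified effect estimation pooled by inverse
variance, and 10-fold cross-validated allele-score weights with
F-statistics.

## The estimators

For SNP *j* with oriented per-allele effects \(\hat\beta_{Xj}\) on 25(OH)D
(nmol/l) and \(\hat\beta_{Yj}\) on diabetes log odds:

- **Wald ratio** (per 25 nmol/l): \(25\,\hat\beta_{Yj}/\hat\beta_{Xj}\),
  first-order delta-method SE.
- **Fixed-effect IVW**:
  \(\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j\), \(w_j = 1/\mathrm{se}_j^2\),
  \(\mathrm{se} = (\sum_j w_j)^{-1/2}\), with Cochran's Q and I².
- **MR-Egger**: weighted regression of \(\hat\beta_{Y}\) on
  \(\hat\beta_{X}\) with a free intercept; the intercept p-value is the
  directional-pleiotropy test.
- **Weighted median**: interpolated median of Wald ratios under
  inverse-variance weights, bootstrap SE; robust while < 50% of the weight
  is invalid.
- **Allele-score IV**: area-stratified logistic regression of diabetes on
  the cross-validated score, rescaled per 25 nmol/l by the score's
  per-allele effect on 25(OH)D.
- **Observational side**: adjusted logistic regression per 25 nmol/l,
  tertiles with floated absolute risks (a standard error for every
  category, reference included), and forward-stepwise confounder entry.
- **Cross-study side**: allele harmonisation, within-study IVW of score-set
  Wald ratios, fixed-effect meta-analysis with northern/southern (50
  degree) latitude subgroups and forest tables.

## Worked example

```r
library(vitdmr)

# A biobank-scale synthetic cohort with a true causal OR of 0.86 per
# 25 nmol/l, using the two synthesis SNPs as instruments
cfg    <- generator_config(snps = ckb_snp_panel()[1:2, ], causal_or_per25 = 0.86)
cohort <- simulate_cohort(cfg, seed = 42)

sm <- cv_weights(cohort, k = 10, seed = 42)  # cross-validated score weights
sm
#> Allele score over 2 SNPs (10-fold cross-validated weights, n = 3014)
#> rs12785878 rs10741657
#>      3.227      1.347
#> Per-allele effect on 25(OH)D: 2.27 (SE 0.25) nmol/l, F = 80.0

score_iv(cohort, sm)                         # causal estimate per 25 nmol/l
#> Effect estimate(s):
#>    method          unit    or ci_low ci_high         p     n n_cases
#>  score_iv per-25-nmol/l 0.869  0.658    1.15 0.3260586 82464    5694
```

The instrument is strong (F = 80, far above the conventional threshold of
10), and the score IV lands on an estimated OR of 0.869 (95% CI 0.658-1.15)
per 25 nmol/l for this seed — the injected 0.86 almost exactly, though a
single biobank-scale replicate carries a wide interval (which is why the
recovery checks average hundreds of seeds). The same cohort supports the per-SNP
table (`per_snp_exposure_effects()`, `per_snp_outcome_effects()`), the
pleiotropy trait scan, and the summary-level estimators
(`mr_all_methods()`); `run_pipeline(demo_run_config(), "out/")` chains every
stage and writes a manifest with file checksums.

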