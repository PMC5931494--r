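---
title: "Methods: Mendelian randomisation of 25(OH)D and type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation of 25(OH)D and type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The scientific problem

Observational cohorts consistently find that people with higher circulating
25-hydroxyvitamin D (25(OH)D) have lower rates of type 2 diabetes, but
25(OH)D is strongly patterned by latitude, season, adiposity and outdoor
activity, so confounding and reverse causality are real threats. Mendelian
randomisation (MR) sidesteps them by using genetic variants as instruments:
genotypes are fixed at conception, so a variant that raises 25(OH)D provides
a randomised, lifelong nudge to vitamin D status. Four SNPs are established
instruments for 25(OH)D, split by mechanism: two *synthesis* variants
(*DHCR7*-rs12785878, *CYP2R1*-rs10741657) act upstream of the biomarker and
are the cleanest instruments, while the *transport* (*GC/DBP*-rs2282679) and
*catabolism* (*CYP24A1*-rs6013897) variants have plausible pleiotropic
pathways (vitamin D binding protein also carries actin; the 24-hydroxylase
pathway also moves phosphate and FGF-23), which is why analyses are run with
and without them and backed by pleiotropy diagnostics.

`vitdmr` implements this full analysis surface as a tested pipeline:
individual-level instrument construction and observational analysis on
synthetic cohorts that emulate a large Chinese biobank, and summary-level MR
and cross-study meta-analysis for the multi-study combinations.

## The synthetic cohort generator

No individual-level data are shipped; every analysis is exercised on
cohorts drawn from an explicit structural model.

**Exposure.** For individual $i$ in area $a$ with genotype dosages $g_{ij}$,

$$X_i = \mu_a + s_{\mathrm{season}(i)} + \sum_j \beta_{Xj} g_{ij} +
\sum_k \gamma_k (c_{ik} - \bar c_k) + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2).$$

Defaults encode the biobank conditions: allele frequencies 0.46, 0.36, 0.84,
0.70 and per-allele effects 2.84, 0.95, 0.51, 3.59 nmol/l for the four SNPs;
a 10-area latitude gradient of $-1.577$ nmol/l per degree over 20-46 degrees
north; season effects of $\pm 5.5$ nmol/l giving the observed 11 nmol/l
winter-summer contrast; and area baselines centred so the overall mean is
62.1 nmol/l. Two calibration points cannot hold simultaneously under a
linear gradient with equal-sized areas: anchoring the area endpoint means at
90 and 49 nmol/l would put the overall mean at 69.5 nmol/l. We keep the
overall mean/SD (62.1/20.2) exact — it is what the downstream estimators
see — and let the endpoint means land at about 82 and 42 nmol/l; the
gradient slope itself matches the printed endpoint difference.

The residual SD defaults to 14.5 nmol/l, chosen once so the *total* SD under
the default 4-SNP configuration is about 20.2: on the variance scale,
genotypes contribute ~9.9, the latitude gradient ~171, season ~15 and
covariate paths ~2.7, leaving $408 - 199 \approx 209$, i.e. a residual SD of
~14.5.

**Covariates and confounding.** Age (truncated normal 51.4 (10.6), 30-79),
sex (60.5% women), BMI 23.7 (3.4), SBP, DBP, waist-hip ratio, body fat,
physical activity and random glucose are drawn at realistic means/SDs. The
joint covariate distribution is not published, so distributions are fixed
and two configuration knobs carry their *effects*: a named vector of effects
on exposure and one on outcome log-odds. The defaults are a mild confounding
scenario (body fat and physical activity touch the exposure; age, sex, body
fat and SBP touch the outcome) deliberately routed through covariates inside
the standard adjustment set, so the adjusted analyses are consistent while
crude estimates visibly differ — which is what the stepwise-adjustment
display is for.

**Outcome.** Case probability is logistic in the true exposure
($\theta$ log-odds per nmol/l, configured as an odds ratio per 25 nmol/l),
any direct per-allele SNP effects (the pleiotropy knob), and centred
covariate effects. The intercept is either fixed or calibrated numerically
(by `uniroot` on the realised linear predictors) to hit a target case
fraction — 5,566/82,464 for the genetic-scale configuration. A configured
fraction of cases (default 496/(496+979)) is labelled prevalent to exercise
the exclusion rule; the incident-analysis configuration
(`ckb_incident_config()`) mirrors the measured subset: n = 13,069, all
measured, no prevalent cases, ~979 incident cases, injected per-25-nmol/l
OR 0.91.

**What the generator does not emulate.** Linkage disequilibrium (the four
instruments are unlinked by design), genotyping error and missingness,
relatedness, survival-time structure of incidence, assay bias (available as
an optional multiplicative knob but defaulting to 0), and any non-linearity
in the exposure-outcome relation. Passing tests therefore demonstrate that
the estimators recover what this structural model injects — not that real
biobank data are free of those complications.

## Observational analysis

`fit_continuous()` fits logistic regression of incident diabetes on measured
25(OH)D/25 with covariate adjustment (default set: age, sex, area, SBP,
physical activity, percent body fat), excluding prevalent cases. Exactly by
construction, the per-25-nmol/l estimate is the per-1-nmol/l estimate scaled
by 25. Confidence intervals use the multiplier 1.959964 and p-values the
normal approximation throughout the package.

`tertile_analysis()` cuts the measured distribution at its empirical 1/3 and
2/3 quantiles (boundary values to the lower tertile) and presents *floated
absolute risks*: with $V$ the $2\times2$ covariance of the two non-reference
log ORs, the floated variances are $f_0 = V_{12}$, $f_1 = V_{11} - f_0$,
$f_2 = V_{22} - f_0$. In the three-category case this reconstruction is
exact — every pairwise contrast variance is recovered — and it gives the
reference tertile its own standard error instead of an artificial zero.
Near-collinear categories (a negative $f$) raise an error rather than
returning nonsense.

`stepwise_adjust()` adds candidates forward by smallest likelihood-ratio
p-value subject to the entry criterion p <= 0.05, recording the exposure
estimate after each step; the LRT (rather than a single-coefficient Wald
test) handles factor covariates cleanly.

## Instruments

Per-SNP exposure effects are linear regressions of measured 25(OH)D on
dosage adjusted for age, sex and season, fitted separately in each area and
pooled by fixed-effect inverse variance; instruments are then oriented so
the effect allele raises the exposure (orientation is idempotent). The same
stratify-then-pool pattern is used for the per-SNP diabetes models
(logistic, prevalent + incident cases), the trait pleiotropy scan, and the
allele-score models; area stratification absorbs population stratification
along the latitude gradient.

**Cross-validated score weights.** Internal weights estimated and applied in
the same sample overfit, inflating apparent instrument strength. We
partition the measured subset into k = 10 seeded folds; each fold's
individuals are scored with weights (joint multivariable regression of
exposure on all score dosages plus covariates, area-pooled) estimated on the
other nine folds. The score is normalised to an allele-count scale,
$S = \sum_j w_j g_j / \bar w$, so its regression slope on exposure is a
"per-allele" effect comparable to single-SNP effects. The per-allele effect,
its SE and the F-statistic come from the regression of exposure on this
cross-validated score; reported weights are the arithmetic fold average (the
consolidation rule is a package choice; fold weights are also returned). A
fold in which some dosage has zero variance triggers an automatic reduction
of k with a warning. The F-statistic is the squared t-ratio of the score
term — the partial F for a single regressor; F > 10 is the conventional
strength threshold, and the default-scale synthesis score clears it
comfortably (F in the 50-80 range across seeds at n = 3,014 measured).

## MR estimators

With oriented per-allele effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$:

- **Wald ratio**: $25\,\hat\beta_{Yj}/\hat\beta_{Xj}$, first-order SE
  $25\,\mathrm{se}(\hat\beta_{Yj})/\hat\beta_{Xj}$ (second-order term behind
  a flag; with F well above 10 the first-order form is standard). A
  denominator below 0.1 nmol/l per allele raises a weak-instrument error
  rather than returning an explosive ratio.
- **Fixed-effect IVW**: precision-weighted mean, identical to intercept-free
  weighted least squares; Cochran's Q and $I^2$ accompany every pool.
- **MR-Egger**: weighted regression of $\hat\beta_{Y}$ on $\hat\beta_{X}$
  with a free intercept (weights $1/\mathrm{se}_Y^2$); the intercept's
  p-value tests directional pleiotropy. SEs carry the usual multiplicative
  inflation $\max(1, \sqrt{\mathrm{RSS}/(J-2)})$; with few instruments and
  the truncation at 1 the test runs slightly conservative, which the
  simulation suite checks (size within [0.02, 0.08] at J = 4, elevated
  rejection under an injected directional pleiotropic effect). One
  structural caveat the suite documents: the intercept test has power only
  against pleiotropy of *low-leverage* instruments. The transport SNP has
  the largest exposure effect of the four, so a direct effect there is
  absorbed into the slope (and inflates the residual scale, making the test
  *more* conservative); a direct effect on the weak catabolism SNP is what
  the intercept detects. Unoriented input is refused, not silently flipped.
- **Weighted median**: ratios ordered, weights normalised, cumulative weight
  assigned at $p_i = (\sum_{k\le i} w_k - w_i/2)/\sum w$, linear
  interpolation to 0.5 (stated explicitly because several conventions
  exist); SE by seeded parametric bootstrap (default 2,000 draws) resampling
  both instrument sides. Consistent while instruments carrying under half
  the weight are invalid.
- **Score IV**: area-stratified logistic regression of diabetes on the
  allele score (age/sex/season adjusted), pooled across areas, then rescaled
  per 25 nmol/l by the score's cross-validated per-allele exposure effect.

The published score F-statistics (21.9 and 93.1) are not reproducible as
$(\hat\beta/\mathrm{se})^2$ of the published score effects (2.87 (0.39) gives
about 54); the exact construction behind those numbers is unstated, so this
package reports the partial F of the score term and does not target them.

## Cross-study meta-analysis

Study rows are harmonised to the exposure-raising allele (swapped-allele
rows sign-flipped; irreconcilable rows rejected). Palindromic A/T and G/C
SNPs are flagged; `harmonize_studies()` excludes them under its strict
default, but `meta_analysis()` opts out of strictness by default because
the catabolism instrument is itself an A/T variant and curated/simulated
tables here are already reported on the exposure-raising strand — strict
mode would bar every 4-SNP analysis. Within-study estimates are fixed-effect
IVW pools of the score-set Wald ratios (with external reference-panel
exposure weights by default, or each study's internal weights); across
studies, fixed-effect IVW with northern (>50 degrees) / southern subgroups.
Fixed-effect algebra makes subgroup-then-pool exactly equal to pooling all
studies, and the forest table's inverse-variance weights sum to 100.

The 10-study design table (`ckb_meta_design()`) is a **synthetic stand-in**:
the source study-level counts are not published in the paper body, so
per-study case/control splits are plausible inventions constrained to the
printed totals (58,312/370,592 overall; 32,796/248,629 for the 7 studies
carrying the catabolism SNP; 5,566 biobank cases). Study-level simulated
summary statistics draw per-allele log ORs around the model-implied values
with $\mathrm{se} = \sqrt{(1/n_\mathrm{cases} + 1/n_\mathrm{controls})/(2pq)}$,
which reproduces the printed biobank per-SNP precision well (e.g. ~0.02 for
the *DHCR7* log OR).

## Numerical choices and degenerate inputs

- One text dialect everywhere: tab-separated, UTF-8 header row, "." decimal,
  `NA` missing; numerics written at 15 significant digits so write-read
  round-trips are exact to at least 12.
- Every stochastic function takes a seed and restores the caller's RNG
  stream on exit, so nested seeded calls cannot silently correlate
  surrounding simulations; identical configuration + seed gives
  byte-identical outputs (checked via file checksums in the pipeline
  manifest).
- Tertile ties go to the lower tertile; empty tertiles and constant traits
  error; monomorphic SNPs return a flagged null Hardy-Weinberg test; areas
  exhibiting separation or non-convergence are dropped from stratified pools
  with a warning, and fewer than two usable areas triggers an unstratified
  fallback.
- Intercept calibration solves the expected case fraction on the realised
  cohort, making prevalence exact in expectation for any configured effect
  structure.

## Problem sizes used by the test suite

The suite regenerates everything in code. The two heavy recovery checks run
at the study's own scale — 300 cohorts of n = 13,069 for the observational
recovery and 300 cohorts of n = 82,464 for the score-IV recovery (about a
second per replicate) — sizes chosen so the Monte-Carlo standard error of
the recovered percent (about 0.3 and 0.8 percentage points respectively)
sits well inside the assessment tolerances of 1 and 2 points. Both
recoveries pool replicate estimates on the log-OR scale before converting to
percent; the score-IV mean runs slightly above the injected 14% (about half
a point) because first-stage estimation noise in the ratio denominator
inflates the ratio slightly and the cross-validated score is a noisier
instrument than the final-weight score — both effects documented rather than
corrected, as they are inherent to the estimator. Property simulations
(estimator equivalences, test size/power, coverage) run at hundreds to a
thousand replicates of small summary sets, which is where those checks are
sharpest per unit time.

## Known limitations

- Fixed-effects meta-analysis only; no random-effects, MR-PRESSO, mode-based
  or multivariable MR estimators.
- The first-stage/outcome asymmetry of the score IV (weights from the
  measured subset, outcome model on the full cohort) mirrors the study
  design but means the reported per-allele score effect is conditional on
  the measured subset's composition.
- The non-linearity check is a quadratic Wald approximation, labelled as
  such; the published trend-test construction is unstated.
- Synthetic covariates are mutually independent given area and season;
  real anthropometric covariates correlate, so adjusted-model behaviour
  under collinearity is not exercised.
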