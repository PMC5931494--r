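#' The four-SNP 25(OH)D instrument panel
#'
#' Reference panel of the four single-nucleotide polymorphisms known to
#' influence plasma 25(OH)D concentration, with their Chinese-population
#' effect-allele frequencies and per-allele effects on 25(OH)D (nmol/l):
#' two synthesis SNPs (*DHCR7*-rs12785878, *CYP2R1*-rs10741657), one
#' transport SNP (*GC/DBP*-rs2282679) and one catabolism SNP
#' (*CYP24A1*-rs6013897). `direct_logOR` is the per-allele effect on diabetes
#' that does **not** act through 25(OH)D (zero by default; set non-zero to
#' simulate pleiotropy of the transport/catabolism SNPs).
#'
#' @return A `data.frame` with one row per SNP: `snp_id`, `gene`, `role`,
#'   `effect_allele`, `other_allele`, `effect_allele_freq`, `beta_exposure`
#'   (nmol/l per effect allele), `se_exposure`, `direct_logOR`.
#' @examples
#' ckb_snp_panel()
#' @export
ckb_snp_panel <- function() {
  data.frame(
    snp_id = c("rs12785878", "rs10741657", "rs6013897", "rs2282679"),
    gene = c("DHCR7", "CYP2R1", "CYP24A1", "GC/DBP"),
    role = c("synthesis", "synthesis", "catabolism", "transport"),
    effect_allele = c("T", "A", "A", "T"),
    other_allele = c("G", "G", "T", "G"),
    effect_allele_freq = c(0.46, 0.36, 0.84, 0.70),
    beta_exposure = c(2.84, 0.95, 0.51, 3.59),
    se_exposure = c(0.41, 0.42, 0.56, 0.44),
    direct_logOR = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Centres used when covariate effects enter exposure/outcome linear
# predictors, so that configured baselines keep their interpretation.
.covariate_centres <- c(
  age = 51.4, sbp = 131.2, dbp = 77.8, bmi = 23.7, whr = 0.88,
  body_fat = 27, physical_activity = 20, random_glucose = 6.1, sex = 0.605
)

#' Build a cohort generator configuration
#'
#' Assembles and validates the full set of parameters that define a synthetic
#' biobank cohort: SNP panel, 10-area latitude gradient, seasonal contrast,
#' residual exposure variation, the causal effect of 25(OH)D on diabetes,
#' mild covariate confounding, outcome prevalence and the measured-exposure
#' subset. Defaults reproduce the structure of the Chinese biobank genetic
#' study: n = 82,464, overall 25(OH)D mean (SD) 62.1 (20.2) nmol/l, a
#' winter-to-summer contrast of 11 nmol/l, a latitude gradient of
#' -1.577 nmol/l per degree (about a two-fold difference across 20-46
#' degrees), ~6.7% diabetes cases and a 3.7% measured subset.
#'
#' @param n_individuals Cohort size.
#' @param snps SNP panel data frame as returned by [ckb_snp_panel()] (any
#'   subset of rows; extra SNPs allowed with the same columns).
#' @param n_areas Number of geographical areas, evenly spanning
#'   `latitude_range`.
#' @param latitude_range Numeric length-2, degrees north.
#' @param latitude_slope Change in mean 25(OH)D per degree of latitude
#'   (nmol/l; negative = lower in the north).
#' @param mean_exposure Target overall mean 25(OH)D (nmol/l); area baselines
#'   are centred so the population mean equals this value.
#' @param season_effects Named additive effects (nmol/l) for the four seasons;
#'   the default gives the observed winter/summer contrast of 11 nmol/l.
#' @param exposure_residual_sd Residual SD of 25(OH)D (nmol/l) after genotype,
#'   area, season and covariate structure; the default 14.5 yields a total SD
#'   of about 20.2 under the default 4-SNP configuration.
#' @param causal_or_per25 Causal odds ratio of diabetes per 25 nmol/l higher
#'   true 25(OH)D (converted internally to log-odds per nmol/l).
#' @param confounder_exposure_effects,confounder_outcome_effects Named
#'   numeric vectors of linear effects of (centred) covariates on exposure
#'   (nmol/l per unit) and on the outcome log-odds. Defaults give a mild
#'   confounding scenario acting through covariates in the standard
#'   adjustment set.
#' @param baseline_outcome_logodds Fixed outcome intercept; if `NULL`
#'   (default) the intercept is calibrated numerically so the expected case
#'   fraction equals `target_case_fraction`.
#' @param target_case_fraction Overall diabetes prevalence (prevalent +
#'   incident) targeted by intercept calibration.
#' @param prevalent_case_fraction Fraction of cases labelled prevalent
#'   (the remainder incident).
#' @param measured_subset_fraction Fraction of the cohort with a biochemical
#'   25(OH)D measurement, in (0, 1].
#' @param assay_sd,assay_bias Additive SD (nmol/l) and multiplicative bias of
#'   the 25(OH)D assay: `measured = (1 + assay_bias) * true + N(0, assay_sd)`.
#' @param freq_latitude_slope Optional change in effect-allele frequency per
#'   degree of latitude (applied to every SNP, clamped to (0.01, 0.99));
#'   default 0.
#' @return A list of class `"generator_config"`.
#' @seealso [simulate_cohort()], [ckb_incident_config()]
#' @examples
#' cfg <- generator_config(n_individuals = 500)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' @export
generator_config <- function(n_individuals = 82464L,
                             snps = ckb_snp_panel(),
                             n_areas = 10L,
                             latitude_range = c(20, 46),
                             latitude_slope = -(90 - 49) / (46 - 20),
                             mean_exposure = 62.1,
                             season_effects = c(winter = -5.5, spring = 0,
                                                summer = 5.5, autumn = 0),
                             exposure_residual_sd = 14.5,
                             causal_or_per25 = 0.86,
                             confounder_exposure_effects =
                               c(body_fat = -0.08, physical_activity = 0.15),
                             confounder_outcome_effects =
                               c(age = 0.04, sex = -0.15, body_fat = 0.02,
                                 sbp = 0.008),
                             baseline_outcome_logodds = NULL,
                             target_case_fraction = 5566 / 82464,
                             prevalent_case_fraction = 496 / (496 + 979),
                             measured_subset_fraction = 3014 / 82464,
                             assay_sd = 0,
                             assay_bias = 0,
                             freq_latitude_slope = 0) {
  stopifnot(is.data.frame(snps), nrow(snps) >= 1)
  req <- c("snp_id", "effect_allele_freq", "beta_exposure", "direct_logOR")
  if (!all(req %in% names(snps)))
    stop("snps must carry columns ", paste(req, collapse = ", "))
  if (any(snps$effect_allele_freq <= 0 | snps$effect_allele_freq >= 1))
    stop("invalid config: effect-allele frequencies must lie in (0, 1)")
  if (exposure_residual_sd < 0)
    stop("invalid config: exposure_residual_sd must be non-negative")
  if (measured_subset_fraction <= 0 || measured_subset_fraction > 1)
    stop("invalid config: measured_subset_fraction must lie in (0, 1]")
  if (!is.null(baseline_outcome_logodds) && !is.finite(baseline_outcome_logodds))
    stop("invalid config: baseline_outcome_logodds must be finite")
  if (causal_or_per25 <= 0 || !is.finite(causal_or_per25))
    stop("invalid config: causal_or_per25 must be positive and finite")
  stopifnot(length(season_effects) == 4, !is.null(names(season_effects)))
  if (prevalent_case_fraction < 0 || prevalent_case_fraction > 1)
    stop("invalid config: prevalent_case_fraction must lie in [0, 1]")

  latitudes <- seq(latitude_range[1], latitude_range[2], length.out = n_areas)
  # Mean genotype contribution; baselines centred so E[exposure] = mean_exposure
  mean_geno <- sum(snps$beta_exposure * 2 * snps$effect_allele_freq)
  baseline <- mean_exposure - mean_geno - mean(season_effects) +
    latitude_slope * (latitudes - mean(latitudes))
  areas <- data.frame(
    area_id = sprintf("area%02d", seq_len(n_areas)),
    latitude = latitudes,
    baseline_exposure = baseline,
    stringsAsFactors = FALSE
  )

  cfg <- list(
    n_individuals = as.integer(n_individuals),
    snps = snps,
    areas = areas,
    season_effects = season_effects,
    exposure_residual_sd = exposure_residual_sd,
    causal_logOR_per_nmol = log(causal_or_per25) / 25,
    confounder_exposure_effects = confounder_exposure_effects,
    confounder_outcome_effects = confounder_outcome_effects,
    baseline_outcome_logodds = baseline_outcome_logodds,
    target_case_fraction = target_case_fraction,
    prevalent_case_fraction = prevalent_case_fraction,
    measured_subset_fraction = measured_subset_fraction,
    assay_sd = assay_sd,
    assay_bias = assay_bias,
    freq_latitude_slope = freq_latitude_slope,
    covariate_centres = .covariate_centres
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Configuration mirroring the measured incident-analysis subset
#'
#' Convenience wrapper around [generator_config()] for the observational
#' incident analysis: 13,069 individuals, all with measured 25(OH)D, no
#' prevalent cases, an expected ~979 incident cases, and an injected causal
#' odds ratio per 25 nmol/l defaulting to 0.91 (the adjusted observational
#' estimate this cohort is designed to exercise).
#'
#' @param n_individuals Cohort size (default 13,069).
#' @param causal_or_per25 Injected per-25-nmol/l odds ratio.
#' @param ... Further arguments passed to [generator_config()].
#' @return A `"generator_config"`.
#' @export
ckb_incident_config <- function(n_individuals = 13069L,
                                causal_or_per25 = 0.91, ...) {
  generator_config(
    n_individuals = n_individuals,
    causal_or_per25 = causal_or_per25,
    target_case_fraction = 979 / 13069,
    prevalent_case_fraction = 0,
    measured_subset_fraction = 1,
    ...
  )
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP's dosages are independent Binomial(2, p) draws; SNPs are mutually
#' independent (the four instruments sit in different genomic regions and are
#' treated as unlinked).
#'
#' @param freqs Numeric vector of effect-allele frequencies in (0, 1),
#'   optionally named by SNP id. Alternatively a matrix with `n` rows and one
#'   column per SNP of per-individual frequencies (used for a
#'   frequency-by-latitude gradient).
#' @param n Number of individuals.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [simulate_cohort()]).
#' @return An `n` x `length(freqs)` integer matrix of dosages in \{0, 1, 2\},
#'   with column names taken from `names(freqs)`.
#' @examples
#' g <- simulate_genotypes(c(rs12785878 = 0.46), n = 1000, seed = 1)
#' mean(g) / 2 # close to 0.46
#' @export
simulate_genotypes <- function(freqs, n, seed = NULL) .with_seed(seed, {
  if (n < 1) stop("n must be at least 1")
  if (is.matrix(freqs)) {
    if (nrow(freqs) != n) stop("frequency matrix must have n rows")
    if (any(freqs <= 0 | freqs >= 1))
      stop("invalid config: allele frequencies must lie in (0, 1)")
    g <- vapply(seq_len(ncol(freqs)),
                function(j) rbinom(n, 2L, freqs[, j]),
                integer(n))
    colnames(g) <- colnames(freqs)
    return(g)
  }
  if (any(freqs <= 0 | freqs >= 1))
    stop("invalid config: allele frequencies must lie in (0, 1)")
  g <- vapply(freqs, function(p) rbinom(n, 2L, p), integer(n))
  if (!is.matrix(g)) g <- matrix(g, nrow = n)
  colnames(g) <- names(freqs)
  g
})

# Baseline covariates: age truncated-normal 30-79, sex (female share 60.5%),
# anthropometry and blood pressure at Table-1-like means/SDs.
.simulate_covariates <- function(n, config) {
  areas <- config$areas
  a_idx <- sample.int(nrow(areas), n, replace = TRUE)
  season <- sample(names(config$season_effects), n, replace = TRUE)
  lo <- pnorm(30, 51.4, 10.6); hi <- pnorm(79, 51.4, 10.6)
  age <- qnorm(runif(n, lo, hi), 51.4, 10.6)
  sex <- ifelse(rbinom(n, 1L, 0.605) == 1L, "female", "male")
  bmi <- rnorm(n, 23.7, 3.4)
  sbp <- 110.6 + 0.4 * age + rnorm(n, 0, 20.8)
  dbp <- rnorm(n, 77.8, 11.2)
  whr <- rnorm(n, 0.88, 0.06)
  body_fat <- pmin(pmax(rnorm(n, 27, 8), 5), 55)
  physical_activity <- rgamma(n, shape = 4, scale = 5)
  random_glucose <- pmax(rnorm(n, 6.1, 2.4), 2.5)
  data.frame(
    area_id = areas$area_id[a_idx],
    latitude = areas$latitude[a_idx],
    season = season,
    age = age, sex = sex, bmi = bmi, sbp = sbp, dbp = dbp, whr = whr,
    body_fat = body_fat, physical_activity = physical_activity,
    random_glucose = random_glucose,
    stringsAsFactors = FALSE
  )
}

# Centred covariate contribution Sum_k eff_k * (x_k - centre_k); sex enters
# as the female indicator centred at its population share.
.covariate_term <- function(covariates, effects, centres) {
  if (length(effects) == 0) return(rep(0, nrow(covariates)))
  term <- rep(0, nrow(covariates))
  for (nm in names(effects)) {
    x <- if (nm == "sex") as.numeric(covariates$sex == "female")
         else covariates[[nm]]
    if (is.null(x)) stop("covariate '", nm, "' not present in cohort")
    ctr <- if (nm %in% names(centres)) centres[[nm]] else 0
    term <- term + effects[[nm]] * (x - ctr)
  }
  term
}

#' Simulate true 25(OH)D exposure
#'
#' Exposure is the sum of the area baseline, the season effect, the per-allele
#' genotype effects, centred covariate effects and Gaussian residual noise:
#' a linear structural model whose coefficients are recovered in expectation
#' by regression of exposure on dosage.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()] with one column
#'   per configured SNP (in panel order).
#' @param config A `"generator_config"`.
#' @param covariates Data frame holding `area_id`, `season` and any covariates
#'   named in `config$confounder_exposure_effects`.
#' @param seed Optional integer seed (`NULL` = current RNG stream).
#' @return Numeric vector of true 25(OH)D (nmol/l).
#' @export
simulate_exposure <- function(genotypes, config, covariates,
                              seed = NULL) .with_seed(seed, {
  if (nrow(genotypes) != nrow(covariates))
    stop("genotype and covariate tables must have matching rows")
  if (ncol(genotypes) != nrow(config$snps))
    stop("genotype columns must match the configured SNP panel")
  if (config$exposure_residual_sd < 0)
    stop("invalid config: negative residual SD")
  base <- config$areas$baseline_exposure[
    match(covariates$area_id, config$areas$area_id)]
  seas <- config$season_effects[covariates$season]
  geno <- as.vector(genotypes %*% config$snps$beta_exposure)
  conf <- .covariate_term(covariates, config$confounder_exposure_effects,
                          config$covariate_centres)
  noise <- if (config$exposure_residual_sd > 0)
    rnorm(nrow(covariates), 0, config$exposure_residual_sd) else 0
  as.numeric(base + seas + geno + conf + noise)
})

# Solve the outcome intercept so the expected case fraction over the realised
# linear predictors equals the target.
.calibrate_intercept <- function(lp, target) {
  f <- function(c0) mean(plogis(lp + c0)) - target
  uniroot(f, interval = c(-30, 10), tol = 1e-10)$root
}

#' Simulate diabetes status
#'
#' Case probability follows a logistic model in the true exposure, any direct
#' (pleiotropic) per-allele genotype effects, and centred covariate effects.
#' A configured fraction of cases is labelled prevalent (doctor-diagnosed at
#' baseline), the remainder incident.
#'
#' @inheritParams simulate_exposure
#' @param exposure True 25(OH)D values (nmol/l).
#' @return Factor with levels `none`, `prevalent`, `incident`.
#' @export
simulate_outcome <- function(exposure, genotypes, covariates, config,
                             seed = NULL) .with_seed(seed, {
  if (!is.finite(config$causal_logOR_per_nmol))
    stop("invalid config: causal effect must be finite")
  lp <- config$causal_logOR_per_nmol * exposure +
    as.vector(genotypes %*% config$snps$direct_logOR) +
    .covariate_term(covariates, config$confounder_outcome_effects,
                    config$covariate_centres)
  c0 <- if (!is.null(config$baseline_outcome_logodds))
    config$baseline_outcome_logodds
  else .calibrate_intercept(lp, config$target_case_fraction)
  case <- rbinom(length(lp), 1L, plogis(lp + c0)) == 1L
  prevalent <- case & (runif(length(lp)) < config$prevalent_case_fraction)
  factor(ifelse(prevalent, "prevalent", ifelse(case, "incident", "none")),
         levels = c("none", "prevalent", "incident"))
})

#' Simulate a complete individual-level cohort
#'
#' Draws genotypes, covariates, true and measured 25(OH)D, and diabetes
#' status under a [generator_config()]. The measured 25(OH)D value is present
#' only for the measured subset (`NA` elsewhere) and equals
#' `(1 + assay_bias) * exposure_true + N(0, assay_sd)`.
#'
#' Identical `config` and `seed` give byte-identical tables.
#'
#' @param config A `"generator_config"`.
#' @param seed Integer seed (mandatory: the cohort is stochastic).
#' @return A `data.frame` with one row per individual: genotype dosage
#'   columns named by `snp_id`, `exposure_true`, `exposure_measured`,
#'   covariates, and `diabetes_status`. The configuration is attached as
#'   attribute `"config"`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_individuals = 300), seed = 7)
#' table(cohort$diabetes_status)
#' @export
simulate_cohort <- function(config, seed) .with_seed(seed, {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_individuals
  covariates <- .simulate_covariates(n, config)

  p <- config$snps$effect_allele_freq
  if (config$freq_latitude_slope != 0) {
    lat_dev <- covariates$latitude - mean(config$areas$latitude)
    pm <- vapply(p, function(pj)
      pmin(pmax(pj + config$freq_latitude_slope * lat_dev, 0.01), 0.99),
      numeric(n))
    colnames(pm) <- config$snps$snp_id
    genotypes <- simulate_genotypes(pm, n)
  } else {
    genotypes <- simulate_genotypes(setNames(p, config$snps$snp_id), n)
  }

  exposure_true <- simulate_exposure(genotypes, config, covariates)
  status <- simulate_outcome(exposure_true, genotypes, covariates, config)

  measured <- rep(FALSE, n)
  n_meas <- max(1L, round(config$measured_subset_fraction * n))
  measured[sample.int(n, n_meas)] <- TRUE
  exposure_measured <- rep(NA_real_, n)
  exposure_measured[measured] <-
    (1 + config$assay_bias) * exposure_true[measured] +
    (if (config$assay_sd > 0) rnorm(n_meas, 0, config$assay_sd) else 0)

  cohort <- cbind(
    data.frame(id = seq_len(n)),
    as.data.frame(genotypes),
    data.frame(exposure_true = exposure_true,
               exposure_measured = exposure_measured,
               stringsAsFactors = FALSE),
    covariates,
    data.frame(diabetes_status = status)
  )
  attr(cohort, "config") <- config
  cohort
})

#' Synthetic 10-study meta-analysis design
#'
#' A stand-in study table for the cross-study meta-analysis: 10 studies (one
#' Chinese, nine European) whose case/control counts are constrained to the
#' published totals (58,312 cases and 370,592 controls overall; 32,796 cases
#' and 248,629 controls in the 7 studies carrying the catabolism SNP; 5,566
#' cases in the Chinese biobank). The per-study split is **synthetic**: the
#' source study-level table is not publicly printed, so individual counts
#' here are plausible inventions constrained to the totals.
#'
#' @return A `data.frame` with columns `study_id`, `latitude_deg`,
#'   `latitude_class` (`northern` > 50 degrees, `southern` otherwise),
#'   `n_cases`, `n_controls`, `has_catabolism_snp`.
#' @export
ckb_meta_design <- function() {
  d <- data.frame(
    study_id = c("CKB", "UKB", "DIAGRAM", "T2D-Exome", "Copenhagen",
                 "EPIC-InterAct-gwas", "EPIC-InterAct-metabochip",
                 "Norfolk-Diabetes", "ADDITION-Ely", "CCCS"),
    latitude_deg = c(33, 53, 52, 52, 55, 52, 52, 52, 52, 52),
    n_cases = c(5566, 24141, 12171, 8000, 2559, 2500, 1500, 1000, 375, 500),
    n_controls = c(76898, 115000, 69731, 60000, 25000, 9000, 6000,
                   4000, 2963, 2000),
    has_catabolism_snp = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                           FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  d$latitude_class <- ifelse(d$latitude_deg > 50, "northern", "southern")
  d
}

#' Simulate per-study SNP summary statistics
#'
#' Generates one row per SNP per study: the per-allele log odds ratio for
#' diabetes drawn about the model-implied value (the common causal
#' per-25-nmol/l effect transmitted through each SNP's effect on 25(OH)D,
#' plus any direct pleiotropic effect), with standard error
#' `sqrt((1/n_cases + 1/n_controls) / (2 p (1-p)))` so that precision grows
#' with study size.
#'
#' @param design Study table as from [ckb_meta_design()]; studies lacking the
#'   catabolism SNP omit its row.
#' @param snps SNP panel (see [ckb_snp_panel()]).
#' @param causal_or_per25 Common causal odds ratio per 25 nmol/l.
#' @param seed Integer seed.
#' @return Long-format `data.frame` of class `"study_summary"`: study fields
#'   plus `snp_id`, `effect_allele`, `other_allele`, `effect_allele_freq`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @export
simulate_study_summaries <- function(design = ckb_meta_design(),
                                     snps = ckb_snp_panel(),
                                     causal_or_per25 = 0.86,
                                     seed) .with_seed(seed, {
  stopifnot(nrow(design) >= 1, all(design$n_cases >= 1),
            all(design$n_controls >= 1))
  causal_per_nmol <- log(causal_or_per25) / 25
  rows <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    st <- design[i, ]
    panel <- snps
    if (!isTRUE(st$has_catabolism_snp) && "role" %in% names(panel))
      panel <- panel[panel$role != "catabolism", ]
    p <- panel$effect_allele_freq
    true_logor <- causal_per_nmol * panel$beta_exposure + panel$direct_logOR
    se <- sqrt((1 / st$n_cases + 1 / st$n_controls) / (2 * p * (1 - p)))
    data.frame(
      study_id = st$study_id,
      latitude_deg = st$latitude_deg,
      latitude_class = st$latitude_class,
      n_cases = st$n_cases, n_controls = st$n_controls,
      snp_id = panel$snp_id,
      effect_allele = panel$effect_allele,
      other_allele = panel$other_allele,
      effect_allele_freq = p,
      beta_exposure = panel$beta_exposure,
      se_exposure = panel$se_exposure,
      beta_outcome = rnorm(nrow(panel), true_logor, se),
      se_outcome = se,
      stringsAsFactors = FALSE
    )
  }))
  class(rows) <- c("study_summary", "data.frame")
  rows
})
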