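# Instrument construction from individual-level data: Hardy-Weinberg checks,
# per-SNP exposure and outcome effects stratified by geographical area and
# pooled by inverse variance, cross-validated allele-score weights with
# F-statistics, and the SNP-by-trait pleiotropy scan.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test comparing observed genotype
#' counts with the proportions p^2, 2pq, q^2 expected at the sample allele
#' frequency.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous reference, heterozygous,
#'   homozygous alternative). Alternatively pass a length-3 vector as `n_AA`.
#' @return A list with `chi2`, `p`, `freq` (sample effect-allele frequency)
#'   and `monomorphic` flag. Monomorphic input returns `chi2 = 0`, `p = 1`
#'   with a warning.
#' @examples
#' hwe_test(25, 50, 25) # exactly at equilibrium
#' hwe_test(50, 0, 50)  # complete heterozygote deficit
#' @export
hwe_test <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  counts <- if (is.null(n_Aa)) n_AA else c(n_AA, n_Aa, n_aa)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be at least 1")
  p <- (2 * counts[3] + counts[2]) / (2 * n) # frequency of the 'a' allele
  if (p == 0 || p == 1) {
    warning("monomorphic SNP: Hardy-Weinberg test not informative")
    return(list(chi2 = 0, p = 1, freq = p, monomorphic = TRUE))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       freq = p, monomorphic = FALSE)
}

#' Hardy-Weinberg checks per SNP and area
#'
#' Applies [hwe_test()] to dosage counts separately within each geographical
#' area and flags deviations at `p < flag_below`.
#'
#' @param cohort Cohort data frame with dosage columns.
#' @param snp_ids SNP dosage columns to test (default: all configured SNPs).
#' @param flag_below Flagging threshold (default 1e-3).
#' @return Data frame: `snp_id`, `area_id`, `n`, `chi2`, `p`, `flagged`.
#' @export
hwe_by_area <- function(cohort, snp_ids = .cohort_snps(cohort),
                        flag_below = 1e-3) {
  out <- do.call(rbind, lapply(snp_ids, function(s) {
    do.call(rbind, lapply(split(cohort[[s]], cohort$area_id), function(g) {
      counts <- tabulate(g + 1L, nbins = 3L)
      ht <- suppressWarnings(hwe_test(counts))
      data.frame(snp_id = s, n = length(g), chi2 = ht$chi2, p = ht$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$area_id <- rep(names(split(cohort[[snp_ids[1]]], cohort$area_id)),
                     times = length(snp_ids))
  out$flagged <- out$p < flag_below
  rownames(out) <- NULL
  out[, c("snp_id", "area_id", "n", "chi2", "p", "flagged")]
}

# Dosage columns present in a cohort (from the attached config, else by
# rs-number naming convention).
.cohort_snps <- function(cohort) {
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) return(intersect(cfg$snps$snp_id, names(cohort)))
  grep("^rs[0-9]+$", names(cohort), value = TRUE)
}

# Area-stratified regression of `response ~ terms` pooled across areas by
# fixed-effect inverse variance. `coef_names` selects which coefficients to
# pool; `family = NULL` fits least squares, otherwise glm. Areas that fail
# (too small, separation, non-convergence, absurd SE) are dropped with a
# warning. Falls back to a single unstratified fit if fewer than two usable
# areas remain.
.stratified_fit <- function(data, response, terms, coef_names,
                            family = NULL, min_area_n = 30,
                            se_cap = 10) {
  f <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit_one <- function(d) {
    fit <- tryCatch(
      if (is.null(family)) lm(f, data = d)
      else glm(f, family = family, data = d),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(NULL)
    if (!is.null(family) && !fit$converged) return(NULL)
    cf <- coef(fit)
    if (any(!coef_names %in% names(cf)) || any(is.na(cf[coef_names])))
      return(NULL)
    V <- vcov(fit)
    se <- sqrt(diag(V)[coef_names])
    if (any(!is.finite(se)) || any(se > se_cap)) return(NULL)
    list(beta = cf[coef_names], se = se)
  }
  pieces <- lapply(split(data, data$area_id), function(d) {
    if (nrow(d) < min_area_n) return(NULL)
    if (!is.null(family) && length(unique(d[[response]])) < 2) return(NULL)
    fit_one(droplevels(d))
  })
  ok <- !vapply(pieces, is.null, logical(1))
  if (sum(ok) < length(pieces) && sum(ok) >= 2)
    warning(sum(!ok), " area(s) dropped from the stratified fit")
  if (sum(ok) < 2) {
    warning("fewer than 2 usable areas: falling back to unstratified fit")
    one <- fit_one(data)
    if (is.null(one)) stop("model could not be fitted in any stratum")
    return(lapply(seq_along(coef_names), function(j)
      list(beta = unname(one$beta[j]), se = unname(one$se[j]),
           Q = 0, n_areas = 1L)))
  }
  pieces <- pieces[ok]
  lapply(seq_along(coef_names), function(j) {
    b <- vapply(pieces, function(p) unname(p$beta[j]), numeric(1))
    s <- vapply(pieces, function(p) unname(p$se[j]), numeric(1))
    pool <- .ivw_pool(b, s)
    list(beta = pool$beta, se = pool$se, Q = pool$Q,
         n_areas = length(pieces))
  })
}

#' Per-SNP effects on measured 25(OH)D
#'
#' Linear regression of measured 25(OH)D on each SNP's dosage, adjusted for
#' age, sex and season, fitted separately within each geographical area and
#' combined by fixed-effect inverse-variance weighting. Estimates are then
#' oriented so the effect allele raises 25(OH)D (alleles and frequency are
#' flipped when the fitted slope is negative).
#'
#' @param cohort Cohort data frame; only the measured subset is used.
#' @param snp_ids Dosage columns to analyse.
#' @param adjust Adjustment covariates (default age, sex, season).
#' @param min_area_n Minimum area size for the stratified fits.
#' @return A `data.frame` of SNP instruments: `snp_id`, `gene`,
#'   `effect_allele`, `other_allele`, `effect_allele_freq`, `beta_exposure`,
#'   `se_exposure`, `p`, `n`, `n_areas`, `flipped`.
#' @examples
#' cohort <- simulate_cohort(generator_config(
#'   n_individuals = 3000, measured_subset_fraction = 1), seed = 2)
#' per_snp_exposure_effects(cohort)
#' @export
per_snp_exposure_effects <- function(cohort, snp_ids = .cohort_snps(cohort),
                                     adjust = c("age", "sex", "season"),
                                     min_area_n = 30) {
  d <- cohort[!is.na(cohort$exposure_measured), , drop = FALSE]
  if (nrow(d) == 0) stop("exposure is missing for every individual")
  cfg <- attr(cohort, "config")
  panel <- if (!is.null(cfg)) cfg$snps else NULL
  out <- do.call(rbind, lapply(snp_ids, function(s) {
    res <- .stratified_fit(d, "exposure_measured", c(s, adjust), s,
                           min_area_n = min_area_n, se_cap = Inf)[[1]]
    info <- if (!is.null(panel) && s %in% panel$snp_id)
      panel[panel$snp_id == s, ] else
      data.frame(gene = NA_character_, effect_allele = NA_character_,
                 other_allele = NA_character_, stringsAsFactors = FALSE)
    eaf <- mean(cohort[[s]]) / 2
    data.frame(
      snp_id = s, gene = info$gene,
      effect_allele = info$effect_allele, other_allele = info$other_allele,
      effect_allele_freq = eaf,
      beta_exposure = res$beta, se_exposure = res$se,
      p = 2 * pnorm(-abs(res$beta / res$se)),
      n = sum(!is.na(d[[s]])), n_areas = res$n_areas,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  orient_instruments(out)
}

#' Orient instruments to the exposure-raising allele
#'
#' Flips effect/other allele, frequency and the sign of `beta_exposure`
#' (and of `beta_outcome` if present) for rows whose exposure effect is
#' negative, so that every instrument's effect allele raises the exposure.
#' Idempotent: already-oriented tables pass through unchanged.
#'
#' @param instruments Data frame with at least `beta_exposure`; optionally
#'   `effect_allele`, `other_allele`, `effect_allele_freq`, `beta_outcome`.
#' @return The oriented data frame with a logical `flipped` column.
#' @export
orient_instruments <- function(instruments) {
  flip <- instruments$beta_exposure < 0
  instruments$flipped <- if ("flipped" %in% names(instruments))
    xor(instruments$flipped, flip) else flip
  if (any(flip)) {
    instruments$beta_exposure[flip] <- -instruments$beta_exposure[flip]
    if ("beta_outcome" %in% names(instruments))
      instruments$beta_outcome[flip] <- -instruments$beta_outcome[flip]
    if (all(c("effect_allele", "other_allele") %in% names(instruments))) {
      ea <- instruments$effect_allele[flip]
      instruments$effect_allele[flip] <- instruments$other_allele[flip]
      instruments$other_allele[flip] <- ea
    }
    if ("effect_allele_freq" %in% names(instruments))
      instruments$effect_allele_freq[flip] <-
        1 - instruments$effect_allele_freq[flip]
  }
  instruments
}

# Joint per-SNP weights on one data subset: multivariable linear regression
# of measured exposure on all dosages plus covariates, per area, pooled by
# inverse variance per SNP.
.joint_snp_weights <- function(d, snp_ids, adjust, min_area_n) {
  res <- .stratified_fit(d, "exposure_measured", c(snp_ids, adjust), snp_ids,
                         min_area_n = min_area_n, se_cap = Inf)
  setNames(vapply(res, `[[`, numeric(1), "beta"), snp_ids)
}

#' Cross-validated allele-score weights
#'
#' Estimates internal allele-score weights by k-fold cross-validation on the
#' measured subset: the subset is partitioned into `k` seeded folds; each
#' fold's individuals receive a weighted score built from per-SNP weights
#' estimated on the other k-1 folds (so no individual's exposure informs
#' their own score weights). The score is normalised to an allele-count
#' scale, `S = sum(w_j g_j) / mean(w)`, and the per-allele score effect and
#' its F-statistic come from the area-stratified, covariate-adjusted
#' regression of measured exposure on the cross-validated score. Final
#' reported weights are the arithmetic mean of the fold weights.
#'
#' @param cohort Cohort data frame.
#' @param snp_ids SNPs entering the score (default: all available).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold partition.
#' @param adjust Adjustment covariates.
#' @param min_area_n Minimum area size for stratified fits.
#' @return An object of class `"score_model"`: list with `snp_ids`,
#'   `weights` (named, nmol/l per allele), `fold_weights` (k x J matrix),
#'   `per_allele_effect`, `se`, `f_statistic`, `n`, `k`.
#' @examples
#' cohort <- simulate_cohort(generator_config(
#'   n_individuals = 1500, measured_subset_fraction = 1), seed = 3)
#' cv_weights(cohort, k = 5, seed = 1)
#' @export
cv_weights <- function(cohort, snp_ids = .cohort_snps(cohort), k = 10,
                       seed, adjust = c("age", "sex", "season"),
                       min_area_n = 30) .with_seed(seed, {
  d <- cohort[!is.na(cohort$exposure_measured), , drop = FALSE]
  if (k < 2) stop("k must be at least 2")
  if (nrow(d) < k) stop("measured subset too small for ", k, " folds")
  fold <- sample(rep_len(seq_len(k), nrow(d)))

  # A fold whose training data has a constant dosage cannot estimate that
  # SNP's weight; reduce k and repartition.
  repeat {
    bad <- any(vapply(seq_len(k), function(f) {
      any(vapply(snp_ids, function(s) var(d[[s]][fold != f]) == 0,
                 logical(1)))
    }, logical(1)))
    if (!bad) break
    k <- k - 1L
    if (k < 2) stop("dosage variance vanishes in every partition")
    warning("zero dosage variance in a training fold: reducing k to ", k)
    fold <- sample(rep_len(seq_len(k), nrow(d)))
  }

  fold_w <- do.call(rbind, lapply(seq_len(k), function(f)
    .joint_snp_weights(d[fold != f, , drop = FALSE], snp_ids, adjust,
                       min_area_n)))
  colnames(fold_w) <- snp_ids

  # Out-of-fold score on the allele-count scale
  d$cv_score <- 0
  for (f in seq_len(k)) {
    w <- fold_w[f, ]
    idx <- fold == f
    d$cv_score[idx] <-
      as.matrix(d[idx, snp_ids, drop = FALSE]) %*% w / mean(w)
  }
  res <- .stratified_fit(d, "exposure_measured", c("cv_score", adjust),
                         "cv_score", min_area_n = min_area_n,
                         se_cap = Inf)[[1]]
  out <- list(
    snp_ids = snp_ids,
    weights = colMeans(fold_w),
    fold_weights = fold_w,
    per_allele_effect = res$beta,
    se = res$se,
    f_statistic = (res$beta / res$se)^2,
    n = nrow(d), k = k, adjust = adjust
  )
  class(out) <- "score_model"
  out
})

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("Allele score over %d SNPs (%d-fold cross-validated weights, n = %d)\n",
              length(x$snp_ids), x$k, x$n))
  print(round(x$weights, 3))
  cat(sprintf("Per-allele effect on 25(OH)D: %.2f (SE %.2f) nmol/l, F = %.1f\n",
              x$per_allele_effect, x$se, x$f_statistic))
  invisible(x)
}

#' Weighted allele score for each individual
#'
#' @param cohort Cohort data frame with the score SNP dosage columns.
#' @param score_model A `"score_model"` from [cv_weights()] (or any list with
#'   `snp_ids` and `weights`).
#' @return Numeric vector: `sum(w_j g_j) / mean(w)` per individual.
#' @export
allele_score <- function(cohort, score_model) {
  missing_cols <- setdiff(score_model$snp_ids, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks score SNP column(s): ",
         paste(missing_cols, collapse = ", "))
  w <- score_model$weights
  as.numeric(as.matrix(cohort[, score_model$snp_ids, drop = FALSE]) %*% w /
               mean(w))
}

#' Per-SNP associations with diabetes
#'
#' Logistic regression of diabetes (prevalent + incident, the convention for
#' genetic analyses) on each SNP's dosage, adjusted for age, sex and season,
#' fitted separately within each area and pooled by fixed-effect inverse
#' variance. Areas exhibiting separation or non-convergence are dropped with
#' a warning.
#'
#' @inheritParams per_snp_exposure_effects
#' @return Data frame: `snp_id`, `beta_outcome` (per-allele log OR),
#'   `se_outcome`, `or`, `ci_low`, `ci_high`, `p`, `n_areas`.
#' @export
per_snp_outcome_effects <- function(cohort, snp_ids = .cohort_snps(cohort),
                                    adjust = c("age", "sex", "season"),
                                    min_area_n = 30) {
  cohort$case <- as.integer(cohort$diabetes_status != "none")
  out <- do.call(rbind, lapply(snp_ids, function(s) {
    res <- .stratified_fit(cohort, "case", c(s, adjust), s,
                           family = binomial(), min_area_n = min_area_n)[[1]]
    data.frame(
      snp_id = s, beta_outcome = res$beta, se_outcome = res$se,
      or = exp(res$beta),
      ci_low = exp(res$beta - Z95 * res$se),
      ci_high = exp(res$beta + Z95 * res$se),
      p = 2 * pnorm(-abs(res$beta / res$se)),
      n_areas = res$n_areas,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' SNP-by-trait pleiotropy scan
#'
#' Area-stratified, covariate-adjusted linear regressions of each
#' cardiometabolic trait on each SNP's dosage, pooled by inverse variance.
#' A clean instrument shows null associations across the trait panel.
#'
#' @inheritParams per_snp_exposure_effects
#' @param traits Trait columns to scan (default: SBP, DBP, BMI, waist-hip
#'   ratio, percent body fat, random glucose).
#' @return Data frame: `snp_id`, `trait`, `effect`, `se`, `p`, `n_areas`.
#' @export
pleiotropy_trait_scan <- function(cohort,
                                  traits = c("sbp", "dbp", "bmi", "whr",
                                             "body_fat", "random_glucose"),
                                  snp_ids = .cohort_snps(cohort),
                                  adjust = c("age", "sex", "season"),
                                  min_area_n = 30) {
  missing_tr <- setdiff(traits, names(cohort))
  if (length(missing_tr) > 0)
    stop("trait(s) not present in cohort: ",
         paste(missing_tr, collapse = ", "))
  out <- do.call(rbind, lapply(traits, function(tr) {
    if (var(cohort[[tr]]) == 0)
      stop("trait '", tr, "' is constant")
    do.call(rbind, lapply(snp_ids, function(s) {
      res <- .stratified_fit(cohort, tr, c(s, adjust), s,
                             min_area_n = min_area_n, se_cap = Inf)[[1]]
      data.frame(snp_id = s, trait = tr, effect = res$beta, se = res$se,
                 p = 2 * pnorm(-abs(res$beta / res$se)),
                 n_areas = res$n_areas, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
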