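# Summary-level and score-based Mendelian randomisation estimators: unit
# conversions, Wald ratios, fixed-effect IVW across SNPs, MR-Egger, the
# weighted median, and the individual-level allele-score IV estimator.

#' Recover a log-OR standard error from a printed confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`, the inverse of the
#' Wald interval construction; used to consume published odds ratios.
#'
#' @param or_point Odds ratio point estimate.
#' @param ci_low,ci_high 95% confidence bounds on the OR scale.
#' @return Standard error of the log odds ratio (vectorised). A zero-width
#'   interval returns `se = 0` with a degeneracy warning.
#' @examples
#' ci_to_se(0.83, 0.79, 0.87)
#' @export
ci_to_se <- function(or_point, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0) || any(or_point <= 0))
    stop("odds ratio and confidence bounds must be positive")
  if (any(ci_low > or_point) || any(or_point > ci_high))
    stop("require ci_low <= or_point <= ci_high")
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  if (any(se == 0)) warning("zero-width interval: degenerate se = 0")
  se
}

#' Rescale a per-allele effect to per 25 nmol/l of exposure
#'
#' Divides the per-allele log OR (and its SE) by the per-allele effect on
#' 25(OH)D and multiplies by 25. First-order scaling: uncertainty in the
#' exposure-side effect is ignored, the standard convention when instrument
#' strength is high.
#'
#' @param beta_per_allele,se Per-allele log OR and its standard error.
#' @param beta_exposure_per_allele Per-allele effect on 25(OH)D (nmol/l);
#'   must be positive (instruments are oriented upstream, see
#'   [orient_instruments()]).
#' @param method Label carried into the result.
#' @return A [new_estimate()] row with unit `"per-25-nmol/l"`.
#' @examples
#' scale_per_25(log(0.97), 0.02, 2.87)
#' @export
scale_per_25 <- function(beta_per_allele, se, beta_exposure_per_allele,
                         method = "scaled") {
  if (any(beta_exposure_per_allele <= 0))
    stop("orientation error: per-allele exposure effect must be positive")
  f <- 25 / beta_exposure_per_allele
  new_estimate(beta_per_allele * f, se * f,
               unit = "per-25-nmol/l", method = method)
}

#' Wald ratio causal estimate for a single instrument
#'
#' The per-25-nmol/l causal log OR is `25 * beta_outcome / beta_exposure`.
#' The default standard error is first-order (delta method, exposure-side
#' uncertainty ignored, justified by strong instruments); the full
#' second-order term is available behind `second_order`.
#'
#' @param beta_exposure,se_exposure Per-allele effect on 25(OH)D (nmol/l)
#'   and SE; `beta_exposure` must exceed `min_beta_exposure`.
#' @param beta_outcome,se_outcome Per-allele log OR for diabetes and SE,
#'   oriented to the exposure-raising allele.
#' @param min_beta_exposure Weak-instrument floor (default 0.1 nmol/l).
#' @param second_order Include the exposure-side variance term in the SE.
#' @return A [new_estimate()] row (`method = "wald"`).
#' @examples
#' wald_ratio(2.84, 0.41, log(0.97), 0.021)
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       min_beta_exposure = 0.1, second_order = FALSE) {
  if (beta_exposure < min_beta_exposure)
    stop("weak instrument: per-allele exposure effect ", beta_exposure,
         " below the minimum ", min_beta_exposure, " nmol/l")
  beta <- 25 * beta_outcome / beta_exposure
  se <- if (second_order)
    25 * sqrt(se_outcome^2 / beta_exposure^2 +
              beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  else 25 * se_outcome / beta_exposure
  new_estimate(beta, se, unit = "per-25-nmol/l", method = "wald")
}

#' Fixed-effect inverse-variance-weighted combination
#'
#' Pools estimates assuming a single common effect:
#' `beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`, `se = 1 / sqrt(sum(1/se_i^2))`,
#' with the Cochran heterogeneity statistic
#' `Q = sum(((b_i - beta)/se_i)^2)`.
#'
#' @param beta,se Numeric vectors of estimates and positive standard errors
#'   (at least 2).
#' @param unit,method Labels carried into the result.
#' @return A [new_estimate()] row with extra columns `n_snps`, `Q`, `I2`.
#' @examples
#' ivw(c(log(0.91), log(0.83)),
#'     c(ci_to_se(0.91, 0.82, 1.00), ci_to_se(0.83, 0.79, 0.87)))
#' @export
ivw <- function(beta, se, unit = "per-25-nmol/l", method = "ivw") {
  if (length(beta) < 2) stop("ivw needs at least 2 estimates")
  if (any(se <= 0)) stop("all standard errors must be positive")
  pool <- .ivw_pool(beta, se)
  out <- new_estimate(pool$beta, pool$se, unit = unit, method = method)
  out$n_snps <- length(beta)
  out$Q <- pool$Q
  out$I2 <- pool$I2
  out
}

#' MR-Egger regression
#'
#' Weighted linear regression of per-allele outcome effects on per-allele
#' exposure effects with a free intercept, weights `1/se_outcome^2`. A
#' non-zero intercept indicates directional pleiotropy; its p-value is the
#' pleiotropy test. Standard errors carry the multiplicative inflation
#' `max(1, sqrt(RSS/(J-2)))`. The slope is rescaled per 25 nmol/l; the
#' intercept is reported per allele.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Per-allele
#'   instrument effects, oriented so every `beta_exposure > 0` (unoriented
#'   input is refused).
#' @return Two-row estimate data frame: methods `egger_slope`
#'   (per-25-nmol/l) and `egger_intercept` (per-allele), with `n_snps`.
#' @export
egger <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  J <- length(beta_exposure)
  if (J < 3) stop("MR-Egger needs at least 3 instruments ",
                  "(a 2-point fit is exact)")
  if (any(beta_exposure <= 0))
    stop("orientation error: all exposure effects must be positive")
  if (any(se_outcome <= 0)) stop("outcome standard errors must be positive")
  w <- 1 / se_outcome^2
  fit <- lm(beta_outcome ~ beta_exposure, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  infl <- max(1, sigma)
  se_raw <- s$coefficients[, "Std. Error"] / sigma * infl
  slope <- coef(fit)["beta_exposure"]
  inter <- coef(fit)["(Intercept)"]
  out <- rbind(
    {
      e <- new_estimate(unname(slope) * 25, unname(se_raw["beta_exposure"]) * 25,
                        unit = "per-25-nmol/l", method = "egger_slope")
      e
    },
    new_estimate(unname(inter), unname(se_raw["(Intercept)"]),
                 unit = "per-allele", method = "egger_intercept")
  )
  out$n_snps <- J
  class(out) <- c("vitdmr_estimate", "data.frame")
  out
}

# Interpolated weighted median: cumulative weights assigned at
# p_i = (cumsum(w)_i - w_i/2) / sum(w), linear interpolation to 0.5.
.weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  i <- max(which(p < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

#' Weighted median MR estimator
#'
#' The weighted median of per-SNP Wald ratios, consistent when instruments
#' carrying less than half the weight are invalid. Weights are the inverse
#' variances of the per-SNP ratio estimates; the point estimate interpolates
#' the cumulative weight distribution at 0.5; the standard error comes from
#' a seeded parametric bootstrap resampling both instrument sides from their
#' normal sampling distributions.
#'
#' @inheritParams egger
#' @param n_boot Bootstrap replications (default 2000).
#' @param seed Mandatory integer seed for the bootstrap.
#' @return A [new_estimate()] row (`method = "weighted_median"`) with
#'   `n_snps` and `bootstrap_reps` columns.
#' @export
weighted_median <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome, n_boot = 2000, seed) {
  J <- length(beta_exposure)
  if (J < 2) stop("weighted median needs at least 2 instruments")
  if (any(beta_exposure <= 0))
    stop("orientation error: all exposure effects must be positive")
  ratios <- 25 * beta_outcome / beta_exposure
  weights <- beta_exposure^2 / (25^2 * se_outcome^2)
  if (sum(weights) <= 0) stop("total weight must be positive")
  est <- .weighted_median_point(ratios, weights)
  boot <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(J, beta_exposure, se_exposure)
    by <- rnorm(J, beta_outcome, se_outcome)
    bx <- pmax(bx, 1e-6) # orientation guard inside the bootstrap
    .weighted_median_point(25 * by / bx, bx^2 / (25^2 * se_outcome^2))
  }, numeric(1)))
  out <- new_estimate(est, sd(boot), unit = "per-25-nmol/l",
                      method = "weighted_median")
  out$n_snps <- J
  out$bootstrap_reps <- n_boot
  out
}

#' Allele-score instrumental-variable estimate
#'
#' The individual-level two-stage estimator: the per-allele association of
#' the cross-validated allele score with diabetes (area-stratified logistic
#' regression pooled by inverse variance, prevalent + incident cases),
#' rescaled per 25 nmol/l by the score's per-allele effect on measured
#' 25(OH)D.
#'
#' @param cohort Cohort data frame carrying all score SNP dosage columns.
#' @param score_model A `"score_model"` from [cv_weights()].
#' @param adjust Covariates for the outcome model.
#' @param min_area_n Minimum area size for stratified fits.
#' @return A [new_estimate()] row (`method = "score_iv"`, per-25-nmol/l)
#'   with attribute `"per_allele"` holding the per-allele score estimate.
#' @examples
#' cfg <- generator_config(n_individuals = 4000,
#'                         measured_subset_fraction = 0.5)
#' cohort <- simulate_cohort(cfg, seed = 5)
#' sm <- cv_weights(cohort, k = 5, seed = 1)
#' score_iv(cohort, sm)
#' @export
score_iv <- function(cohort, score_model,
                     adjust = c("age", "sex", "season"), min_area_n = 30) {
  cohort$score <- allele_score(cohort, score_model)
  cohort$case <- as.integer(cohort$diabetes_status != "none")
  res <- .stratified_fit(cohort, "case", c("score", adjust), "score",
                         family = binomial(), min_area_n = min_area_n)[[1]]
  per_allele <- new_estimate(res$beta, res$se, unit = "per-allele",
                             method = "score_logistic",
                             n = nrow(cohort),
                             n_cases = sum(cohort$case))
  out <- scale_per_25(res$beta, res$se, score_model$per_allele_effect,
                      method = "score_iv")
  out$n <- nrow(cohort)
  out$n_cases <- sum(cohort$case)
  attr(out, "per_allele") <- per_allele
  out
}

#' Run the summary-level MR toolbox on an instrument table
#'
#' Convenience wrapper applying Wald ratios per SNP, fixed-effect IVW,
#' MR-Egger (when at least 3 instruments) and the weighted median to an
#' oriented instrument table.
#'
#' @param instruments Data frame with `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (see
#'   [orient_instruments()]).
#' @param methods Subset of `c("wald", "ivw", "egger", "median")`.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @return Estimate data frame, one row per method (per-SNP Wald rows are
#'   labelled `wald:<snp_id>`).
#' @export
mr_all_methods <- function(instruments,
                           methods = c("wald", "ivw", "egger", "median"),
                           n_boot = 2000, seed = 1) {
  if (any(instruments$beta_exposure <= 0))
    stop("orientation error: run orient_instruments() first")
  bx <- instruments$beta_exposure; sx <- instruments$se_exposure
  by <- instruments$beta_outcome; sy <- instruments$se_outcome
  out <- NULL
  if ("wald" %in% methods) {
    wr <- do.call(rbind, lapply(seq_len(nrow(instruments)), function(i) {
      e <- wald_ratio(bx[i], sx[i], by[i], sy[i])
      e$method <- paste0("wald:", instruments$snp_id[i])
      e
    }))
    out <- wr
  }
  add <- function(out, e) {
    if (is.null(out)) return(e)
    for (cl in setdiff(names(e), names(out))) out[[cl]] <- NA
    for (cl in setdiff(names(out), names(e))) e[[cl]] <- NA
    rbind(out, e[names(out)])
  }
  if ("ivw" %in% methods && nrow(instruments) >= 2) {
    ratios <- 25 * by / bx; ses <- 25 * sy / bx
    out <- if (is.null(out)) ivw(ratios, ses) else add(out, ivw(ratios, ses))
  }
  if ("egger" %in% methods && nrow(instruments) >= 3)
    out <- add(out, egger(bx, sx, by, sy))
  if ("median" %in% methods && nrow(instruments) >= 2)
    out <- add(out, weighted_median(bx, sx, by, sy, n_boot = n_boot,
                                    seed = seed))
  rownames(out) <- NULL
  class(out) <- c("vitdmr_estimate", "data.frame")
  out
}
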