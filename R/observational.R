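# Observational association of measured 25(OH)D with incident diabetes:
# continuous per-25-nmol/l logistic estimates, tertiles with floated absolute
# risks, and forward-stepwise covariate adjustment.

# Build the analysis subset: measured exposure, optional prevalent-case
# exclusion. Outcome is incident diabetes when prevalent cases are excluded,
# any diabetes otherwise.
.observational_data <- function(cohort, exclude_prevalent) {
  d <- cohort[!is.na(cohort$exposure_measured), , drop = FALSE]
  if (nrow(d) == 0) stop("no individuals with measured exposure")
  if (exclude_prevalent) {
    d <- d[d$diabetes_status != "prevalent", , drop = FALSE]
    d$case <- as.integer(d$diabetes_status == "incident")
  } else {
    d$case <- as.integer(d$diabetes_status != "none")
  }
  for (v in c("sex", "season", "area_id"))
    if (v %in% names(d)) d[[v]] <- factor(d[[v]])
  d
}

.rhs <- function(covariates) {
  if (length(covariates) == 0) "1" else paste(covariates, collapse = " + ")
}

#' Continuous observational estimate per 25 nmol/l higher 25(OH)D
#'
#' Logistic regression of diabetes on measured 25(OH)D (scaled to
#' 25-nmol/l units) with covariate adjustment. By default prevalent cases are
#' excluded and the outcome is incident diabetes, the convention for the
#' observational analysis (the genetic analyses keep all cases).
#'
#' @param cohort Cohort data frame from [simulate_cohort()] (or read with
#'   [read_cohort()]); only rows with measured exposure are used.
#' @param covariates Character vector of adjustment covariates; `area_id`,
#'   `sex` and `season` are entered as factors. The default is the standard
#'   adjustment set: age, sex, latitude (area), SBP, physical activity and
#'   percent body fat.
#' @param exclude_prevalent Drop doctor-diagnosed baseline cases (default
#'   `TRUE`).
#' @param per Exposure scaling in nmol/l (default 25).
#' @return A [new_estimate()] row with unit `"per-25-nmol/l"` (or
#'   `"per-<per>-nmol/l"`).
#' @examples
#' cohort <- simulate_cohort(ckb_incident_config(n_individuals = 2000), seed = 1)
#' fit_continuous(cohort)
#' @export
fit_continuous <- function(cohort,
                           covariates = c("age", "sex", "area_id", "sbp",
                                          "physical_activity", "body_fat"),
                           exclude_prevalent = TRUE, per = 25) {
  d <- .observational_data(cohort, exclude_prevalent)
  d$exposure_scaled <- d$exposure_measured / per
  f <- as.formula(paste("case ~ exposure_scaled +", .rhs(covariates)))
  fit <- tryCatch(glm(f, family = binomial(), data = d),
                  error = function(e)
                    stop("logistic fit failed with covariates {",
                         paste(covariates, collapse = ", "), "}: ",
                         conditionMessage(e)))
  if (!fit$converged)
    stop("logistic fit did not converge with covariates {",
         paste(covariates, collapse = ", "), "}")
  b <- coef(fit)["exposure_scaled"]
  se <- sqrt(vcov(fit)["exposure_scaled", "exposure_scaled"])
  new_estimate(unname(b), unname(se),
               unit = sprintf("per-%g-nmol/l", per),
               method = "observational-logistic",
               n = nrow(d), n_cases = sum(d$case))
}

#' Floated variances for a three-category exposure
#'
#' Re-parameterises the covariance matrix of the two non-reference log odds
#' ratios into independent "floated" variances, one per category including
#' the reference: `f0 = Cov(b1, b2)`, `f1 = Var(b1) - f0`,
#' `f2 = Var(b2) - f0`. In the three-category case this reconstruction is
#' exact: `f0 + f_i = Var(b_i)` and `f1 + f2 = Var(b1 - b2)`.
#'
#' @param coef_cov Symmetric positive-definite 2 x 2 covariance matrix of the
#'   non-reference category log odds ratios.
#' @return Numeric vector `c(f0, f1, f2)` of floated variances.
#' @examples
#' floated_variances(matrix(c(2, 1, 1, 2), 2))
#' @export
floated_variances <- function(coef_cov) {
  if (!is.matrix(coef_cov) || any(dim(coef_cov) != 2))
    stop("coef_cov must be a 2 x 2 matrix")
  if (abs(coef_cov[1, 2] - coef_cov[2, 1]) > 1e-8 * max(abs(coef_cov), 1))
    stop("coef_cov must be symmetric")
  ev <- eigen(coef_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("coef_cov must be positive definite")
  f0 <- coef_cov[1, 2]
  f <- c(f0, coef_cov[1, 1] - f0, coef_cov[2, 2] - f0)
  if (any(f < 0))
    stop("degenerate covariance: floated variances would be negative ",
         "(near-collinear categories)")
  names(f) <- c("f0", "f1", "f2")
  f
}

#' Tertile analysis with floated absolute risks
#'
#' Splits the measured exposure at its empirical tertile cut points (boundary
#' values assigned to the lower tertile), fits an adjusted logistic model
#' with two tertile indicators, and converts the fitted covariance into
#' floated absolute risks so every tertile - including the reference - gets
#' its own standard error and confidence interval.
#'
#' @inheritParams fit_continuous
#' @return A `data.frame` with one row per tertile: `tertile`, `range`, `n`,
#'   `n_events`, `or_floated` (reference = 1), `se_floated`, `ci_low`,
#'   `ci_high`.
#' @export
tertile_analysis <- function(cohort,
                             covariates = c("age", "sex", "area_id", "sbp",
                                            "physical_activity", "body_fat"),
                             exclude_prevalent = TRUE) {
  d <- .observational_data(cohort, exclude_prevalent)
  if (length(unique(d$exposure_measured)) < 3)
    stop("need at least 3 distinct exposure values for tertiles")
  qs <- quantile(d$exposure_measured, c(1, 2) / 3, names = FALSE)
  d$tertile <- cut(d$exposure_measured, c(-Inf, qs, Inf),
                   labels = c("T1", "T2", "T3"), right = TRUE)
  if (any(table(d$tertile) == 0)) stop("empty tertile")
  f <- as.formula(paste("case ~ tertile +", .rhs(covariates)))
  fit <- glm(f, family = binomial(), data = d)
  idx <- c("tertileT2", "tertileT3")
  b <- coef(fit)[idx]
  fv <- floated_variances(vcov(fit)[idx, idx])
  or <- c(1, exp(b))
  sef <- sqrt(fv)
  data.frame(
    tertile = c("T1", "T2", "T3"),
    range = c(sprintf("<=%.1f", qs[1]),
              sprintf("(%.1f, %.1f]", qs[1], qs[2]),
              sprintf(">%.1f", qs[2])),
    n = as.integer(table(d$tertile)),
    n_events = as.integer(tapply(d$case, d$tertile, sum)),
    or_floated = unname(or),
    se_floated = unname(sef),
    ci_low = unname(exp(log(or) - Z95 * sef)),
    ci_high = unname(exp(log(or) + Z95 * sef)),
    stringsAsFactors = FALSE
  )
}

#' Forward-stepwise covariate adjustment
#'
#' Starting from the unadjusted exposure model, repeatedly adds the candidate
#' covariate with the smallest likelihood-ratio p-value while that p-value is
#' at most `p_entry`, recording the exposure estimate after each step. This
#' reproduces the sequential-adjustment display in which the exposure-disease
#' association is tracked as confounders enter.
#'
#' @inheritParams fit_continuous
#' @param candidates Character vector of candidate covariates.
#' @param p_entry Entry criterion (default 0.05).
#' @return A `data.frame` with one row per model (first row = base model):
#'   `step`, `added` (`NA` for the base model), `p_added`, and the exposure
#'   estimate columns of [new_estimate()].
#' @export
stepwise_adjust <- function(cohort, candidates, p_entry = 0.05,
                            exclude_prevalent = TRUE, per = 25) {
  if (length(candidates) == 0) stop("candidate list must be non-empty")
  d <- .observational_data(cohort, exclude_prevalent)
  d$exposure_scaled <- d$exposure_measured / per

  fit_with <- function(covs) {
    glm(as.formula(paste("case ~ exposure_scaled +", .rhs(covs))),
        family = binomial(), data = d)
  }
  exposure_est <- function(fit, step, added, p_added) {
    b <- coef(fit)["exposure_scaled"]
    se <- sqrt(vcov(fit)["exposure_scaled", "exposure_scaled"])
    cbind(data.frame(step = step, added = added, p_added = p_added,
                     stringsAsFactors = FALSE),
          as.data.frame(new_estimate(unname(b), unname(se),
                                     unit = sprintf("per-%g-nmol/l", per),
                                     method = "stepwise-logistic",
                                     n = nrow(d), n_cases = sum(d$case))))
  }

  selected <- character(0)
  current <- fit_with(selected)
  out <- exposure_est(current, 0L, NA_character_, NA_real_)
  remaining <- candidates
  step <- 0L
  while (length(remaining) > 0) {
    pvals <- vapply(remaining, function(cv) {
      cand <- tryCatch(fit_with(c(selected, cv)), error = function(e) NULL)
      if (is.null(cand) || !cand$converged) return(NA_real_)
      anova(current, cand, test = "LRT")[2, "Pr(>Chi)"]
    }, numeric(1))
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) > p_entry) break
    best <- remaining[which.min(pvals)]
    selected <- c(selected, best)
    current <- fit_with(selected)
    step <- step + 1L
    out <- rbind(out, exposure_est(current, step, best,
                                   min(pvals, na.rm = TRUE)))
    remaining <- setdiff(remaining, best)
  }
  rownames(out) <- NULL
  out
}

#' Quadratic test of non-linearity (approximation)
#'
#' Wald test of a quadratic exposure term added to the adjusted continuous
#' model. The construction of the published trend/non-linearity test is not
#' fully specified; this quadratic Wald test is offered as a labelled
#' approximation.
#'
#' @inheritParams fit_continuous
#' @return A list with `p_nonlinearity` and the quadratic coefficient and SE.
#' @export
nonlinearity_test <- function(cohort,
                              covariates = c("age", "sex", "area_id", "sbp",
                                             "physical_activity", "body_fat"),
                              exclude_prevalent = TRUE) {
  d <- .observational_data(cohort, exclude_prevalent)
  d$e1 <- d$exposure_measured / 25
  d$e2 <- d$e1^2
  fit <- glm(as.formula(paste("case ~ e1 + e2 +", .rhs(covariates))),
             family = binomial(), data = d)
  b <- coef(fit)["e2"]
  se <- sqrt(vcov(fit)["e2", "e2"])
  list(beta_quadratic = unname(b), se = unname(se),
       p_nonlinearity = unname(2 * pnorm(-abs(b / se))),
       note = "quadratic Wald approximation")
}
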