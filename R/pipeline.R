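# Delimited-text I/O and the end-to-end pipeline. One dialect everywhere:
# tab-separated, UTF-8, "." decimal, "NA" missing, header row, full numeric
# precision (15 significant digits).

.write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  for (cl in names(x)[num]) x[[cl]] <- format(x[[cl]], digits = 15,
                                              scientific = FALSE, trim = TRUE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", na.strings = "NA", stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write / read a cohort table
#'
#' Tab-separated with a header row; missing measured exposure written as
#' `NA`. Numeric fields round-trip to at least 12 significant digits.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns the path invisibly; `read_cohort` the
#'   cohort data frame (diabetes status restored as a factor).
#' @export
write_cohort <- function(cohort, path) .write_tsv(cohort, path)

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- .read_tsv(path)
  if ("diabetes_status" %in% names(d))
    d$diabetes_status <- factor(d$diabetes_status,
                                levels = c("none", "prevalent", "incident"))
  d
}

#' Read and validate a study summary table
#'
#' Strictly typed reader for per-study per-SNP summary rows. Accepts either
#' `beta_outcome`/`se_outcome` columns or `or`/`ci_low`/`ci_high` columns
#' (converted via [ci_to_se()]). Rows failing validation are collected with
#' their line numbers and dropped; if more than `max_bad_fraction` of data
#' rows fail, reading aborts.
#'
#' @param path File path (dialect: tab-separated, `NA` missing token).
#' @param max_bad_fraction Abort threshold for the rejected-row fraction.
#' @return The validated data frame with `beta_outcome`/`se_outcome`
#'   populated; rejected rows (with `line` and `reason`) are attached as
#'   attribute `"rejected"`.
#' @export
read_summary_table <- function(path, max_bad_fraction = 0.2) {
  d <- tryCatch(.read_tsv(path),
                error = function(e) stop("malformed table ", path, ": ",
                                         conditionMessage(e)))
  required <- c("study_id", "snp_id", "effect_allele", "other_allele")
  if (!all(required %in% names(d)))
    stop("malformed header: need columns ", paste(required, collapse = ", "))
  if (nrow(d) == 0) {
    attr(d, "rejected") <- data.frame(line = integer(0),
                                      reason = character(0))
    return(d)
  }
  has_beta <- all(c("beta_outcome", "se_outcome") %in% names(d))
  has_or <- all(c("or", "ci_low", "ci_high") %in% names(d))
  if (!has_beta && !has_or)
    stop("malformed header: need beta_outcome/se_outcome or or/ci_low/ci_high")

  reason <- rep(NA_character_, nrow(d))
  if (!has_beta) {
    d$beta_outcome <- NA_real_
    d$se_outcome <- NA_real_
  }
  for (i in seq_len(nrow(d))) {
    if (has_or && (!has_beta || is.na(d$beta_outcome[i]))) {
      ok <- is.finite(d$or[i]) && is.finite(d$ci_low[i]) &&
        is.finite(d$ci_high[i]) && d$ci_low[i] > 0 &&
        d$ci_low[i] <= d$or[i] && d$or[i] <= d$ci_high[i]
      if (!ok) {
        reason[i] <- "invalid or/ci_low/ci_high triple"
        next
      }
      d$beta_outcome[i] <- log(d$or[i])
      d$se_outcome[i] <- ci_to_se(d$or[i], d$ci_low[i], d$ci_high[i])
    }
    if (!is.finite(d$beta_outcome[i]) || !is.finite(d$se_outcome[i]) ||
        d$se_outcome[i] <= 0)
      reason[i] <- "missing or non-positive beta_outcome/se_outcome"
  }
  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + 1L, # +1 for the header row
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " row(s) rejected while reading ", path)
  if (mean(bad) > max_bad_fraction)
    stop("more than ", round(100 * max_bad_fraction),
         "% of rows failed validation in ", path)
  out <- d[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Default small pipeline run configuration
#'
#' A demonstration configuration with a reduced cohort so the full pipeline
#' completes in seconds.
#'
#' @param n_individuals Cohort size for the demo.
#' @param seed Run seed.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_run_config <- function(n_individuals = 4000, seed = 1) {
  list(
    stages = c("simulate", "observational", "instruments", "mr", "meta"),
    generator = generator_config(n_individuals = n_individuals,
                                 measured_subset_fraction = 0.5),
    incident_generator = ckb_incident_config(n_individuals = n_individuals),
    covariates = c("age", "sex", "area_id", "sbp", "physical_activity",
                   "body_fat"),
    score_set = "synthesis",
    k = 5,
    mr_methods = c("wald", "ivw", "egger", "median"),
    n_boot = 500,
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in the pre-specified order - simulate,
#' observational, instruments, MR, meta - writing each stage's tables under
#' `out_dir` and a JSON manifest recording inputs, seeds, per-stage row
#' counts and file checksums. Re-running with an identical configuration and
#' seed reproduces byte-identical outputs.
#'
#' @param config Run configuration (see [demo_run_config()]); `seed` is
#'   mandatory whenever a stochastic stage is enabled.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = demo_run_config(), out_dir) {
  stages <- config$stages
  known <- c("simulate", "observational", "instruments", "mr", "meta")
  if (length(setdiff(stages, known)) > 0)
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (length(stages) > 0 && is.null(config$seed))
    stop("seed is mandatory when any stochastic stage is enabled")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("vitdmr")),
                   seed = config$seed, stages = as.list(stages),
                   outputs = list())
  note <- function(stage, files, rows) {
    manifest$outputs[[stage]] <<- list(
      files = as.list(basename(files)),
      rows = rows,
      md5 = as.list(unname(md5sum(files))))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- NULL; inc_cohort <- NULL; studies <- NULL
  if ("simulate" %in% stages) run_stage("simulate", {
    cohort <- simulate_cohort(config$generator, seed = config$seed)
    inc_cohort <- simulate_cohort(config$incident_generator,
                                  seed = config$seed + 1L)
    studies <- simulate_study_summaries(seed = config$seed + 2L)
    f <- file.path(out_dir, c("cohort.tsv", "incident_cohort.tsv",
                              "studies.tsv"))
    write_cohort(cohort, f[1]); write_cohort(inc_cohort, f[2])
    .write_tsv(studies, f[3])
    note("simulate", f, c(nrow(cohort), nrow(inc_cohort), nrow(studies)))
  })
  if ("observational" %in% stages) run_stage("observational", {
    if (is.null(inc_cohort)) stop("no cohort available (enable simulate)")
    est <- fit_continuous(inc_cohort, covariates = config$covariates)
    tert <- tertile_analysis(inc_cohort, covariates = config$covariates)
    f <- file.path(out_dir, c("observational.tsv", "tertiles.tsv"))
    .write_tsv(as.data.frame(est), f[1]); .write_tsv(tert, f[2])
    note("observational", f, c(nrow(est), nrow(tert)))
  })
  score_model <- NULL; instr <- NULL
  if ("instruments" %in% stages) run_stage("instruments", {
    if (is.null(cohort)) stop("no cohort available (enable simulate)")
    exp_eff <- per_snp_exposure_effects(cohort)
    out_eff <- per_snp_outcome_effects(cohort)
    snps <- intersect(score_set_snps(config$score_set),
                      .cohort_snps(cohort))
    score_model <- cv_weights(cohort, snp_ids = snps, k = config$k,
                              seed = config$seed + 3L)
    instr <- merge(exp_eff, out_eff, by = "snp_id")
    hwe <- hwe_by_area(cohort)
    f <- file.path(out_dir, c("instruments.tsv", "hwe.tsv", "score.tsv"))
    .write_tsv(instr, f[1]); .write_tsv(hwe, f[2])
    .write_tsv(data.frame(snp_id = score_model$snp_ids,
                          weight = score_model$weights,
                          per_allele_effect = score_model$per_allele_effect,
                          se = score_model$se,
                          f_statistic = score_model$f_statistic), f[3])
    note("instruments", f, c(nrow(instr), nrow(hwe),
                             length(score_model$snp_ids)))
  })
  if ("mr" %in% stages) run_stage("mr", {
    if (is.null(instr)) stop("no instruments available (enable instruments)")
    mr <- mr_all_methods(instr, methods = config$mr_methods,
                         n_boot = config$n_boot, seed = config$seed + 4L)
    siv <- score_iv(cohort, score_model)
    mr <- rbind(mr, cbind(as.data.frame(siv),
                          setNames(as.data.frame(
                            matrix(NA, 1, length(setdiff(names(mr),
                                                         names(siv))))),
                            setdiff(names(mr), names(siv))))[names(mr)])
    f <- file.path(out_dir, "mr.tsv")
    .write_tsv(mr, f)
    note("mr", f, nrow(mr))
  })
  if ("meta" %in% stages) run_stage("meta", {
    if (is.null(studies)) stop("no study table available (enable simulate)")
    meta <- meta_analysis(studies, score_set = config$score_set)
    ft <- forest_table(meta)
    f <- file.path(out_dir, c("meta.tsv", "forest.tsv"))
    .write_tsv(as.data.frame(meta$pooled), f[1]); .write_tsv(ft, f[2])
    note("meta", f, c(1L, nrow(ft)))
  })

  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
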