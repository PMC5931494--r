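# Cross-study meta-analysis: allele harmonisation, within-study weighted
# combination of per-SNP Wald ratios, fixed-effect pooling with latitude
# subgroups, and forest-table output.

# Named SNP sets used for the genetic scores
.score_sets <- list(
  synthesis = c("rs12785878", "rs10741657"),
  synthesis_transport = c("rs12785878", "rs10741657", "rs2282679"),
  all4 = c("rs12785878", "rs10741657", "rs2282679", "rs6013897"),
  synthesis_catabolism = c("rs12785878", "rs10741657", "rs6013897"),
  lead_pair = c("rs12785878", "rs2282679")
)

#' SNPs belonging to a named score set
#'
#' Score sets: `synthesis` (the two synthesis SNPs; the primary analysis),
#' `synthesis_transport` (the three SNPs available in all studies), `all4`
#' (secondary analysis), `synthesis_catabolism`, and `lead_pair` (lead
#' synthesis + transport SNP).
#'
#' @param score_set Score-set name.
#' @return Character vector of SNP ids.
#' @export
score_set_snps <- function(score_set = names(.score_sets)) {
  score_set <- match.arg(score_set)
  .score_sets[[score_set]]
}

.ambiguous_pair <- function(a, b) {
  pair <- paste(pmin(a, b), pmax(a, b))
  pair %in% c("A T", "C G")
}

#' Harmonise study rows to the exposure-raising allele
#'
#' Aligns each study x SNP row to the reference instrument orientation: rows
#' already on the exposure-raising allele pass through; rows with swapped
#' alleles have their outcome effect sign-flipped and frequency complemented;
#' rows whose alleles cannot be reconciled are rejected. Strand-ambiguous
#' palindromic pairs (A/T, G/C) are flagged and, under `strict` (default),
#' excluded.
#'
#' @param rows Long-format study table (as from
#'   [simulate_study_summaries()] or [read_summary_table()]) with
#'   `snp_id`, `effect_allele`, `other_allele`, `beta_outcome`; optionally
#'   `effect_allele_freq`.
#' @param reference Reference instrument table with `snp_id`,
#'   `effect_allele`, `other_allele` oriented to raise the exposure
#'   (default [ckb_snp_panel()]).
#' @param strict Exclude strand-ambiguous SNPs (default `TRUE`).
#' @return The input with a `status` column (`ok`, `flipped`, `ambiguous`,
#'   `rejected`) and effects aligned for rows with status `ok`/`flipped`.
#'   Use [harmonized_ok()] to keep the usable rows.
#' @export
harmonize_studies <- function(rows, reference = ckb_snp_panel(),
                              strict = TRUE) {
  rows$status <- "rejected"
  for (i in seq_len(nrow(rows))) {
    j <- match(rows$snp_id[i], reference$snp_id)
    if (is.na(j)) next
    ea <- rows$effect_allele[i]; oa <- rows$other_allele[i]
    ref_ea <- reference$effect_allele[j]; ref_oa <- reference$other_allele[j]
    ambiguous <- .ambiguous_pair(ea, oa)
    if (ea == ref_ea && oa == ref_oa) {
      rows$status[i] <- if (ambiguous && strict) "ambiguous" else "ok"
    } else if (ea == ref_oa && oa == ref_ea) {
      rows$effect_allele[i] <- ref_ea
      rows$other_allele[i] <- ref_oa
      rows$beta_outcome[i] <- -rows$beta_outcome[i]
      if ("effect_allele_freq" %in% names(rows))
        rows$effect_allele_freq[i] <- 1 - rows$effect_allele_freq[i]
      rows$status[i] <- if (ambiguous && strict) "ambiguous" else "flipped"
    }
  }
  rows
}

#' Keep harmonised rows usable for analysis
#' @param rows Output of [harmonize_studies()].
#' @return Rows with status `ok` or `flipped`.
#' @export
harmonized_ok <- function(rows) {
  rows[rows$status %in% c("ok", "flipped"), , drop = FALSE]
}

#' Per-study causal estimate from a SNP score set
#'
#' Converts each of a study's per-allele SNP log ORs into a per-25-nmol/l
#' Wald ratio using the exposure-side weights, then combines the ratios
#' within the study by fixed-effect inverse variance. This is the default
#' within-study combination; the alternative score-level combination is not
#' distinguishable from it under fixed-effect weighting of the same SNPs.
#'
#' @param study_rows Harmonised rows for one study.
#' @param score_set Score-set name (see [score_set_snps()]).
#' @param weights Optional named vector of per-SNP exposure effects (nmol/l
#'   per allele) to use as external weights; default uses each row's
#'   `beta_exposure` column.
#' @return A [new_estimate()] row, or `NULL` (with a message) if the study
#'   lacks any score-set SNP.
#' @export
study_estimate <- function(study_rows, score_set = "synthesis",
                           weights = NULL) {
  snps <- score_set_snps(score_set)
  idx <- match(snps, study_rows$snp_id)
  if (any(is.na(idx))) {
    message("study ", study_rows$study_id[1], " lacks SNP(s) ",
            paste(snps[is.na(idx)], collapse = ", "),
            " and is excluded from score set '", score_set, "'")
    return(NULL)
  }
  d <- study_rows[idx, , drop = FALSE]
  bx <- if (is.null(weights)) d$beta_exposure else unname(weights[d$snp_id])
  if (any(is.na(bx) | bx <= 0))
    stop("missing or unoriented exposure weight for score set")
  ratios <- 25 * d$beta_outcome / bx
  ses <- 25 * d$se_outcome / bx
  if (length(ratios) == 1) {
    out <- new_estimate(ratios, ses, unit = "per-25-nmol/l",
                        method = paste0("study:", score_set))
  } else {
    out <- ivw(ratios, ses, method = paste0("study:", score_set))
  }
  out$n <- sum(d$n_cases[1], d$n_controls[1], na.rm = TRUE)
  out$n_cases <- d$n_cases[1]
  out
}

#' Fixed-effect meta-analysis across studies with latitude subgroups
#'
#' Pools per-study per-25-nmol/l estimates by fixed-effect inverse variance,
#' overall and within latitude subgroups (`northern` > 50 degrees,
#' `southern` otherwise), reporting Cochran's Q and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param per_study Data frame with one row per study: `study_id`, `beta`,
#'   `se`, and optionally `latitude_class`, `n_cases`.
#' @param subgroup_by Column to subgroup on, or `NULL` for no subgroups.
#' @return A list of class `"meta_result"`: `pooled`, `subgroups` (named
#'   list of estimates), `by_study`, `Q`, `df`, `I2`.
#' @export
combine_studies <- function(per_study, subgroup_by = "latitude_class") {
  if (nrow(per_study) == 0) stop("no studies to combine")
  pool <- .ivw_pool(per_study$beta, per_study$se)
  pooled <- new_estimate(pool$beta, pool$se, unit = "per-25-nmol/l",
                         method = "meta-fixed")
  pooled$n_studies <- nrow(per_study)
  subgroups <- list()
  if (!is.null(subgroup_by) && subgroup_by %in% names(per_study) &&
      length(unique(per_study[[subgroup_by]])) > 1) {
    subgroups <- lapply(split(per_study, per_study[[subgroup_by]]),
                        function(d) {
      sp <- .ivw_pool(d$beta, d$se)
      e <- new_estimate(sp$beta, sp$se, unit = "per-25-nmol/l",
                        method = "meta-fixed-subgroup")
      e$n_studies <- nrow(d)
      e
    })
  }
  out <- list(pooled = pooled, subgroups = subgroups, by_study = per_study,
              Q = pool$Q, df = pool$df, I2 = pool$I2)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis of %d studies: OR %.3f (95%% CI %.3f-%.3f) per 25 nmol/l\n",
    x$pooled$n_studies, x$pooled$or, x$pooled$ci_low, x$pooled$ci_high))
  cat(sprintf("Q = %.2f on %d df, I2 = %.1f%%\n", x$Q, x$df, x$I2))
  for (nm in names(x$subgroups))
    cat(sprintf("  %s: OR %.3f (%.3f-%.3f), %d studies\n", nm,
                x$subgroups[[nm]]$or, x$subgroups[[nm]]$ci_low,
                x$subgroups[[nm]]$ci_high, x$subgroups[[nm]]$n_studies))
  invisible(x)
}

#' Forest table for a meta-analysis result
#'
#' One row per study ordered by subgroup, with odds ratio, confidence bounds
#' and the percent inverse-variance weight (weights sum to 100), followed by
#' subgroup and overall pooled rows.
#'
#' @param meta A `"meta_result"` from [combine_studies()].
#' @return A `data.frame` with columns `row_type`, `subgroup`, `study_id`,
#'   `or`, `ci_low`, `ci_high`, `weight_pct`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  d <- meta$by_study
  if (!"latitude_class" %in% names(d)) d$latitude_class <- "all"
  w <- (1 / d$se^2) / sum(1 / d$se^2) * 100
  studies <- data.frame(
    row_type = "study",
    subgroup = d$latitude_class,
    study_id = d$study_id,
    or = exp(d$beta),
    ci_low = exp(d$beta - Z95 * d$se),
    ci_high = exp(d$beta + Z95 * d$se),
    weight_pct = w,
    stringsAsFactors = FALSE
  )
  studies <- studies[order(studies$subgroup, studies$study_id), ]
  pools <- do.call(rbind, c(
    lapply(names(meta$subgroups), function(nm) {
      e <- meta$subgroups[[nm]]
      data.frame(row_type = "subgroup", subgroup = nm, study_id = "",
                 or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
                 weight_pct = NA_real_, stringsAsFactors = FALSE)
    }),
    list(data.frame(row_type = "overall", subgroup = "", study_id = "",
                    or = meta$pooled$or, ci_low = meta$pooled$ci_low,
                    ci_high = meta$pooled$ci_high, weight_pct = NA_real_,
                    stringsAsFactors = FALSE))
  ))
  out <- rbind(studies, pools)
  rownames(out) <- NULL
  out
}

#' Meta-analyse a long study table for one score set
#'
#' End-to-end summary-level path: harmonise rows to the reference
#' orientation, form each study's per-25-nmol/l estimate from the score-set
#' SNPs, and pool across studies with latitude subgroups. Studies lacking a
#' score-set SNP are excluded with a message.
#'
#' @param rows Long study table (see [harmonize_studies()]).
#' @param score_set Score-set name (see [score_set_snps()]).
#' @param weights `"external"` (default: reference-panel exposure effects) or
#'   `"internal"` (use each row's own `beta_exposure`).
#' @param reference Reference instrument panel.
#' @param exclude Optional character vector of `study_id`s to drop (e.g.
#'   overlapping cohorts).
#' @param strict Exclude strand-ambiguous palindromic SNPs during
#'   harmonisation. Defaults to `FALSE` here because curated and simulated
#'   study tables report alleles on the exposure-raising strand (the
#'   catabolism SNP is itself an A/T palindrome, so strict mode would bar
#'   every 4-SNP analysis); set `TRUE` for external tables of uncertain
#'   strand.
#' @return A `"meta_result"` (see [combine_studies()]).
#' @export
meta_analysis <- function(rows, score_set = "synthesis",
                          weights = c("external", "internal"),
                          reference = ckb_snp_panel(), exclude = NULL,
                          strict = FALSE) {
  weights <- match.arg(weights)
  rows <- harmonized_ok(harmonize_studies(rows, reference, strict = strict))
  if (!is.null(exclude)) rows <- rows[!rows$study_id %in% exclude, ]
  wvec <- if (weights == "external")
    setNames(reference$beta_exposure, reference$snp_id) else NULL
  per_study <- do.call(rbind, lapply(split(rows, rows$study_id), function(d) {
    e <- study_estimate(d, score_set, weights = wvec)
    if (is.null(e)) return(NULL)
    data.frame(study_id = d$study_id[1],
               latitude_class = if ("latitude_class" %in% names(d))
                 d$latitude_class[1] else NA_character_,
               beta = e$beta, se = e$se, n_cases = e$n_cases,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_study) || nrow(per_study) == 0)
    stop("no study carries the requested score set")
  combine_studies(per_study)
}
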