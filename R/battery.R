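#' Run the cohort statistical battery
#'
#' Reproduces the study's analysis sequence on an assembled cohort table:
#' a 2x2 mixed ANOVA on movement rates (group x arm) with follow-up paired
#' t tests (Bayes factor attached for the control group's null), the
#' Mann-Whitney comparison of MMR across groups, the Spearman correlation
#' between MMR and the daily-use score, the one-sample t test of embodiment
#' against zero, the embodiment-group comparison of MMR, subgroup checks
#' (cause of limb loss, passive vs active prosthesis), and the Type III
#' ANCOVA of MMR on cause, prosthesis class and daily use.
#'
#' Outlier handling is flag-based: rows flagged by [outlier_flags()] on the
#' one-handers' MMR, or named in `exclude_ids`, are excluded from the
#' parametric ANCOVA only, and listed in the result; nonparametric tests
#' keep all rows.
#'
#' @param cohort A `gesture_cohort` data.frame (see [simulate_cohort()] or
#'   [cohort_table()]).
#' @param exclude_ids Participant ids excluded from parametric analyses by
#'   name (the flag-based rule still applies on top).
#' @param r_scale JZS prior scale for Bayes factors (default 0.707).
#' @param outlier_k MAD multiplier for the outlier rule (default 3).
#' @return Named list of class `stat_battery`.
#' @export
run_stat_battery <- function(cohort, exclude_ids = character(),
                             r_scale = sqrt(2) / 2, outlier_k = 3) {
  oh <- cohort[cohort$group == "one_hander", , drop = FALSE]
  th <- cohort[cohort$group == "two_hander", , drop = FALSE]
  # a failed component is reported, never silently dropped
  try_stat <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stat_result(name, c(value = NA_real_), p = NA_real_,
                  options = list(failed = conditionMessage(e))))
  }
  long <- data.frame(
    id = rep(cohort$participant_id, 2),
    group = rep(cohort$group, 2),
    arm = rep(c("preferred", "nonpreferred"), each = nrow(cohort)),
    value = c(cohort$moves_per_min_arm1, cohort$moves_per_min_arm2))
  res <- list()
  res$moves_anova <- try_stat("rm_anova", mixed_anova_2x2(long))
  res$moves_paired_onehanders <- try_stat("t_paired",
    t_test_paired(oh$moves_per_min_arm1, oh$moves_per_min_arm2,
                  r_scale = r_scale))
  res$moves_paired_twohanders <- try_stat("t_paired",
    t_test_paired(th$moves_per_min_arm1, th$moves_per_min_arm2,
                  r_scale = r_scale))
  res$u_mmr_group <- try_stat("mann_whitney",
    mann_whitney_u(oh$mmr, th$mmr))
  use_ok <- !is.na(oh$mmr) & !is.na(oh$daily_use_score)
  res$spearman_mmr_use <- try_stat("spearman",
    spearman_cor(oh$mmr[use_ok], oh$daily_use_score[use_ok]))
  res$t_embodiment <- try_stat("t_one_sample",
    t_test_one(oh$embodiment_score, r_scale = r_scale))
  pos <- oh$embodiment_group == "positive"
  res$u_mmr_embodiment <- try_stat("mann_whitney",
    mann_whitney_u(oh$mmr[pos], oh$mmr[!pos]))
  cong <- oh$cause == "congenital"
  res$u_mmr_cause <- try_stat("mann_whitney",
    mann_whitney_u(oh$mmr[cong], oh$mmr[!cong]))
  lat_moves <- oh$moves_per_min_arm1 - oh$moves_per_min_arm2
  res$u_moveslat_cause <- try_stat("mann_whitney",
    mann_whitney_u(lat_moves[cong], lat_moves[!cong]))
  passive <- oh$prosthesis_type == "cosmetic"
  res$u_mmr_prosthesis <- try_stat("mann_whitney",
    mann_whitney_u(oh$mmr[passive], oh$mmr[!passive]))
  res$u_moveslat_prosthesis <- try_stat("mann_whitney",
    mann_whitney_u(lat_moves[passive], lat_moves[!passive]))
  # parametric ANCOVA: flag-based outlier exclusion on the laterality measure
  flags <- rep(FALSE, nrow(oh))
  ok_mmr <- !is.na(oh$mmr)
  if (sum(ok_mmr) >= 5)
    flags[ok_mmr] <- outlier_flags(oh$mmr[ok_mmr], k = outlier_k)
  named <- oh$participant_id %in% exclude_ids
  keep <- !flags & !named & ok_mmr
  adf <- oh[keep, , drop = FALSE]
  adf$prosthesis_class <- ifelse(adf$prosthesis_type == "cosmetic",
                                 "passive", "active")
  res$ancova <- try_stat("ancova",
    ancova_terms(adf, response = "mmr",
                 fixed = c("cause", "prosthesis_class"),
                 covariate = "daily_use_score"))
  excl <- data.frame(
    participant_id = oh$participant_id[flags | named],
    value = oh$mmr[flags | named],
    rule = ifelse(named[flags | named], "named exclusion",
                  sprintf("|value - median| > %g MAD", outlier_k)))
  structure(c(res, list(parametric_exclusions = excl)),
            class = "stat_battery")
}

#' @export
print.stat_battery <- function(x, ...) {
  cat("Cohort statistical battery\n==========================\n")
  show <- function(r) {
    if (inherits(r, "stat_result")) print(r)
    else if (is.list(r)) lapply(r, show)
    invisible(NULL)
  }
  for (nm in setdiff(names(x), "parametric_exclusions")) show(x[[nm]])
  ex <- x$parametric_exclusions
  if (nrow(ex)) {
    cat("Parametric-analysis exclusions (kept in nonparametric tests):\n")
    for (i in seq_len(nrow(ex)))
      cat(sprintf("  %s: value %.3f (%s)\n", ex$participant_id[i],
                  ex$value[i], ex$rule[i]))
  } else cat("No parametric-analysis exclusions.\n")
  invisible(x)
}

#' Assemble a cohort table from metrics and questionnaire scores
#'
#' @param metrics List of `gesture_metrics` (one per participant).
#' @param scores Data.frame from [score_questionnaires()] (one-handers
#'   only; controls may be absent).
#' @param meta Data.frame with `participant_id`, `group`, `cause`,
#'   `prosthesis_type`.
#' @return A `gesture_cohort` data.frame with flagged (never dropped)
#'   missing-metric exclusions.
#' @export
cohort_table <- function(metrics, scores, meta) {
  mrow <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(participant_id = m$participant_id,
               moves_per_min_arm1 = m$moves_per_min_arm1,
               moves_per_min_arm2 = m$moves_per_min_arm2,
               mmr = as.numeric(m$mmr),
               mmr_reason = attr(m$mmr, "reason") %||% NA_character_,
               n_active_epochs = m$n_active_epochs)
  }))
  df <- merge(meta, mrow, by = "participant_id", all.x = TRUE)
  df <- merge(df, scores, by = "participant_id", all.x = TRUE)
  df$excluded <- !is.na(df$mmr_reason)
  df$exclusion_reason <- df$mmr_reason
  df$mmr_reason <- NULL
  df <- df[order(df$group, df$participant_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gesture_cohort", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
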