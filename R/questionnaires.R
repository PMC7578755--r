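#' Score the PAL functional-use items
#'
#' Mean of the item responses normalized to `[0, 1]` (0 = minimum function,
#' 1 = maximum function). Missing items are excluded from the mean; a score
#' is only produced when at most 20% of items are missing.
#'
#' @param pal_items Numeric vector of item responses in `[0, item_scale_max]`
#'   (`NA` allowed).
#' @param item_scale_max Maximum of the item response scale.
#' @param max_missing Largest tolerated missing fraction (default 0.2).
#' @return Score in `[0, 1]`, or flagged `NA` when too much is missing.
#' @export
score_pal <- function(pal_items, item_scale_max, max_missing = 0.2) {
  stopifnot(length(pal_items) >= 1, item_scale_max > 0)
  ok <- !is.na(pal_items)
  if (any(pal_items[ok] < 0 | pal_items[ok] > item_scale_max))
    stop("PAL responses outside [0, ", item_scale_max, "]")
  if (mean(!ok) > max_missing)
    return(structure(NA_real_,
                     reason = sprintf("%d/%d PAL items missing",
                                      sum(!ok), length(pal_items))))
  mean(pal_items[ok]) / item_scale_max
}

#' Score perceived embodiment
#'
#' Arithmetic mean of the five embodiment statements, each rated from -3
#' (strongly disagree) to +3 (strongly agree), 0 neutral.
#'
#' @param embodiment_items Exactly 5 responses in `[-3, 3]` (half steps or
#'   any real in range accepted).
#' @return The mean, in `[-3, 3]`.
#' @export
score_embodiment <- function(embodiment_items) {
  if (length(embodiment_items) != 5L)
    stop("embodiment score needs exactly 5 item responses, got ",
         length(embodiment_items))
  if (anyNA(embodiment_items) ||
      any(embodiment_items < -3 | embodiment_items > 3))
    stop("embodiment responses must lie in [-3, 3]")
  mean(embodiment_items)
}

#' Embodiment group assignment
#'
#' Participants are split by whether their embodiment score is positive
#' (> 0) or neutral/negative (<= 0); a score of exactly 0 falls in the
#' neutral/negative group.
#'
#' @param embodiment_score Finite score in `[-3, 3]`.
#' @return `"positive"` or `"neutral_negative"`.
#' @export
embodiment_group <- function(embodiment_score) {
  stopifnot(all(is.finite(embodiment_score)))
  ifelse(embodiment_score > 0, "positive", "neutral_negative")
}

#' Composite daily prosthesis-use score
#'
#' Weekly wear hours and PAL functional use have incommensurate units, so
#' the composite is the mean of their within-cohort z-scores (a rank-average
#' alternative is available; Spearman-based analyses are invariant to the
#' choice when both components are monotone). Both raw components should
#' always be reported alongside the composite.
#'
#' @param wear_hours_week Vector of weekly wear hours for the whole cohort
#'   (0-168).
#' @param pal_score Vector of PAL scores in `[0, 1]` for the same cohort.
#' @param method `"zscore"` (default) or `"rank"` (mean of centred ranks,
#'   scaled to unit sd).
#' @return Numeric vector of composite scores (cohort mean 0 by
#'   construction); entries with a missing component are `NA`. If a
#'   component is degenerate (zero variance) it is dropped with a warning.
#' @export
daily_use_score <- function(wear_hours_week, pal_score,
                            method = c("zscore", "rank")) {
  method <- match.arg(method)
  stopifnot(length(wear_hours_week) == length(pal_score))
  if (any(wear_hours_week < 0 | wear_hours_week > 168, na.rm = TRUE))
    stop("wear hours outside [0, 168]")
  comp <- list(wear = wear_hours_week, pal = pal_score)
  zs <- lapply(comp, function(v) {
    if (method == "rank") {
      r <- rank(v, na.last = "keep")
      v <- r
    }
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(NULL)
    (v - mean(v, na.rm = TRUE)) / s
  })
  drop <- vapply(zs, is.null, logical(1))
  if (all(drop)) stop("both daily-use components are degenerate")
  if (any(drop))
    warning("degenerate daily-use component dropped: ",
            paste(names(comp)[drop], collapse = ", "))
  zmat <- do.call(cbind, zs[!drop])
  out <- rowMeans(zmat)        # NA when any retained component is missing
  out
}

#' Engagement check on the control statement
#'
#' The control statement ("it seems like I have three hands") should be
#' strongly rejected; a response above the cutoff flags possible
#' non-engagement with the questionnaire.
#'
#' @param control_item Response in `[-3, 3]`.
#' @param cutoff Responses strictly above this flag non-engagement
#'   (default -1).
#' @return Logical: `TRUE` when engagement looks fine, `FALSE` when flagged.
#' @export
check_control_item <- function(control_item, cutoff = -1) {
  stopifnot(all(control_item >= -3 & control_item <= 3))
  control_item <= cutoff
}

#' Score a questionnaire table
#'
#' Takes one row per participant with columns `participant_id`,
#' `wear_hours_week`, PAL items `pal_01..`, embodiment items
#' `emb_01..emb_05` and `control_item`, and returns all derived scores.
#' The daily-use composite is standardized within the supplied table
#' (the cohort context).
#'
#' @param df Questionnaire data.frame.
#' @param pal_scale_max Maximum of the PAL item scale.
#' @return A data.frame with `participant_id`, `wear_hours_week`,
#'   `pal_score`, `daily_use_score`, `embodiment_score`,
#'   `embodiment_group`, `control_ok`.
#' @export
score_questionnaires <- function(df, pal_scale_max) {
  pal_cols <- grep("^pal_", names(df), value = TRUE)
  emb_cols <- grep("^emb_", names(df), value = TRUE)
  if (length(emb_cols) != 5L)
    stop("expected 5 embodiment item columns emb_01..emb_05, found ",
         length(emb_cols))
  pal <- apply(df[, pal_cols, drop = FALSE], 1, score_pal,
               item_scale_max = pal_scale_max)
  emb <- apply(df[, emb_cols, drop = FALSE], 1, score_embodiment)
  data.frame(participant_id = df$participant_id,
             wear_hours_week = df$wear_hours_week,
             pal_score = pal,
             daily_use_score = daily_use_score(df$wear_hours_week, pal),
             embodiment_score = emb,
             embodiment_group = embodiment_group(emb),
             control_ok = check_control_item(df$control_item))
}
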