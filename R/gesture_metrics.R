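#' Detect movement bouts in a gravity-removed signal
#'
#' A movement is a maximal run of suprathreshold magnitude lasting at least
#' `min_dur_s`, after merging subthreshold gaps shorter than `merge_gap_s`.
#' The count of such bouts depends on the (arbitrary) threshold, which is why
#' it is always reported alongside the threshold used.
#'
#' @param fsig A `filtered_signal` from [remove_gravity()], or a numeric
#'   magnitude vector (then `fs` must be given).
#' @param threshold_g Detection threshold in g (> 0; default 0.05).
#' @param min_dur_s Minimum bout duration in seconds (default 0.25).
#' @param merge_gap_s Subthreshold gaps shorter than this are absorbed into
#'   the surrounding bout (default 0.25).
#' @param windows Optional [task_windows()]; detection is then restricted to
#'   each window separately (bouts never span windows).
#' @param fs Sampling rate, only needed when `fsig` is a bare vector.
#' @return A `data.frame` of movement events: `arm_role`, `start_s`, `end_s`,
#'   `peak_mag_g`, `mean_mag_g`, ordered by start time.
#' @export
detect_movements <- function(fsig, threshold_g = 0.05, min_dur_s = 0.25,
                             merge_gap_s = 0.25, windows = NULL, fs = NULL) {
  stopifnot(threshold_g > 0)
  if (is.numeric(fsig)) {
    if (is.null(fs)) stop("fs required for a bare magnitude vector")
    fsig <- list(mag = fsig, fs = fs, t0 = 0, arm_role = NA_character_)
  }
  if (is.null(windows)) {
    segs <- list(seq_along(fsig$mag))
  } else {
    segs <- lapply(seq_len(nrow(windows)), function(w) {
      k0 <- max(ceiling((windows$start_s[w] - fsig$t0) * fsig$fs - 1e-9), 0)
      k1 <- min(ceiling((windows$end_s[w] - fsig$t0) * fsig$fs - 1e-9) - 1,
                length(fsig$mag) - 1)
      if (k1 < k0) integer(0) else (k0 + 1L):(k1 + 1L)
    })
  }
  out <- lapply(segs, function(ix) {
    if (!length(ix)) return(NULL)
    detect_runs(fsig$mag[ix], fsig$fs, threshold_g, min_dur_s, merge_gap_s,
                t_offset = fsig$t0 + (ix[1L] - 1L) / fsig$fs,
                arm_role = fsig$arm_role)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(arm_role = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_mag_g = numeric(0),
                      mean_mag_g = numeric(0))
  out[order(out$start_s), , drop = FALSE]
}

detect_runs <- function(mag, fs, threshold_g, min_dur_s, merge_gap_s,
                        t_offset, arm_role) {
  above <- mag >= threshold_g
  if (!any(above)) {
    return(NULL)
  }
  r <- rle(above)
  # absorb interior subthreshold gaps shorter than merge_gap_s
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    gap <- interior[!r$values[interior] &
                      r$lengths[interior] / fs < merge_gap_s]
    r$values[gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= min_dur_s)
  if (!any(keep)) return(NULL)
  data.frame(arm_role = arm_role,
             start_s = t_offset + (starts[keep] - 1L) / fs,
             end_s = t_offset + ends[keep] / fs,
             peak_mag_g = vapply(which(keep), function(i)
               max(mag[starts[i]:ends[i]]), numeric(1)),
             mean_mag_g = vapply(which(keep), function(i)
               mean(mag[starts[i]:ends[i]]), numeric(1)))
}

#' Movement rate per minute
#'
#' @param events Event data.frame from [detect_movements()].
#' @param total_task_s Total task time in seconds (> 0).
#' @return `60 * nrow(events) / total_task_s`.
#' @export
movements_per_minute <- function(events, total_task_s) {
  if (total_task_s <= 0) stop("total task time must be positive")
  60 * nrow(events) / total_task_s
}

#' Per-epoch log magnitude ratios
#'
#' For every epoch where at least one arm is active, the log ratio
#' `log(mag_nonpreferred) - log(mag_preferred)` of the two arms' epoch
#' magnitudes. The nonpreferred arm is the prosthesis (one-handers) or the
#' nondominant arm (controls); positive ratios therefore mean the
#' prosthesis/nondominant arm moved more. Unilateral epochs (exactly one arm
#' active) receive `+cap` when only the nonpreferred arm is active and `-cap`
#' when only the preferred arm is; bilateral ratios are clamped to the same
#' bounds. Epochs where neither arm is active are excluded.
#'
#' @param epochs An [epoch_series()] (arm 1 preferred, arm 2 nonpreferred).
#' @param cap Bound for unilateral epochs and for clamping (default 7).
#' @return Numeric vector of per-epoch ratios over the active epochs.
#' @export
magnitude_ratio_series <- function(epochs, cap = 7) {
  stopifnot(inherits(epochs, "epoch_series"), cap > 0)
  a1 <- epochs$active_arm1
  a2 <- epochs$active_arm2
  keep <- a1 | a2
  r <- numeric(sum(keep))
  both <- (a1 & a2)[keep]
  only2 <- (!a1 & a2)[keep]
  m1 <- epochs$mag_arm1[keep]
  m2 <- epochs$mag_arm2[keep]
  # difference of logs (not log of quotient) so role-swapping negates exactly
  r[both] <- pmin(pmax(log(m2[both]) - log(m1[both]), -cap), cap)
  r[only2] <- cap
  r[!both & !only2] <- -cap
  r
}

#' Median magnitude ratio (MMR)
#'
#' The median of the per-epoch log magnitude ratios over active epochs:
#' 0 means both arms contribute equally to movement size; negative values
#' mean the intact/dominant arm produced larger movements.
#'
#' @param ratios Per-epoch ratios from [magnitude_ratio_series()].
#' @param min_active_epochs Minimum number of active epochs for a valid MMR
#'   (default 10); below that `NA` is returned with a `reason` attribute
#'   rather than a silent zero.
#' @return The sample median (mean of the middle two for even length), or
#'   flagged `NA`.
#' @export
median_magnitude_ratio <- function(ratios, min_active_epochs = 10) {
  if (length(ratios) < min_active_epochs) {
    return(structure(NA_real_,
                     reason = sprintf("only %d active epochs (minimum %d)",
                                      length(ratios), min_active_epochs)))
  }
  stats::median(ratios)
}

#' Alternative laterality indices
#'
#' Two simpler laterality summaries of an epoch series, reported alongside
#' the MMR as robustness checks. `use_ratio` is the count of active
#' nonpreferred epochs over the count of active preferred epochs (the bilateral
#' arm-use convention); `laterality_index` is `(M_np - M_p) / (M_np + M_p)`
#' over the summed active-epoch magnitudes, bounded in `[-1, 1]`.
#'
#' @param epochs An [epoch_series()].
#' @param metric `"use_ratio"` or `"laterality_index"`.
#' @return A scalar; flagged `NA` (with `reason` attribute) on a zero
#'   denominator.
#' @export
alternative_laterality <- function(epochs,
                                   metric = c("use_ratio",
                                              "laterality_index")) {
  stopifnot(inherits(epochs, "epoch_series"))
  metric <- match.arg(metric)
  if (metric == "use_ratio") {
    den <- sum(epochs$active_arm1)
    if (den == 0)
      return(structure(NA_real_, reason = "no active preferred-arm epochs"))
    return(sum(epochs$active_arm2) / den)
  }
  m_p <- sum(epochs$mag_arm1[epochs$active_arm1])
  m_np <- sum(epochs$mag_arm2[epochs$active_arm2])
  if (m_p + m_np == 0)
    return(structure(NA_real_, reason = "no active epochs"))
  (m_np - m_p) / (m_np + m_p)
}

#' Compute all gesture metrics for one session
#'
#' Runs gravity removal, epoching, movement detection and the laterality
#' measures over a session's task windows, pooled across windows.
#'
#' @param session A [build_session()] result.
#' @param epoch_len_s,activity_threshold_g,method,cutoff_hz Passed to
#'   [epoch_magnitudes()].
#' @param threshold_g,min_dur_s,merge_gap_s Passed to [detect_movements()].
#' @param cap,min_active_epochs Passed to the ratio computations.
#' @return An object of class `gesture_metrics`: per-arm movement rates,
#'   `mmr`, active/unilateral epoch counts, the two alternative indices,
#'   the full parameter set used, and a fingerprint of it.
#' @export
compute_gesture_metrics <- function(session, epoch_len_s = 1,
                                    activity_threshold_g = 0.01,
                                    method = "highpass", cutoff_hz = 0.25,
                                    threshold_g = 0.05, min_dur_s = 0.25,
                                    merge_gap_s = 0.25, cap = 7,
                                    min_active_epochs = 10) {
  stopifnot(inherits(session, "bimanual_session"),
            nrow(session$windows) >= 1)
  epochs <- epoch_magnitudes(session, epoch_len_s, activity_threshold_g,
                             method, cutoff_hz)
  f1 <- remove_gravity(session$recording_a, method, cutoff_hz)
  f2 <- remove_gravity(session$recording_b, method, cutoff_hz)
  total_s <- sum(session$windows$end_s - session$windows$start_s)
  ev1 <- detect_movements(f1, threshold_g, min_dur_s, merge_gap_s,
                          windows = session$windows)
  ev2 <- detect_movements(f2, threshold_g, min_dur_s, merge_gap_s,
                          windows = session$windows)
  ratios <- magnitude_ratio_series(epochs, cap)
  config <- list(epoch_len_s = epoch_len_s,
                 activity_threshold_g = activity_threshold_g,
                 method = method, cutoff_hz = cutoff_hz,
                 threshold_g = threshold_g, min_dur_s = min_dur_s,
                 merge_gap_s = merge_gap_s, cap = cap,
                 min_active_epochs = min_active_epochs)
  structure(list(participant_id = session$participant_id,
                 role_map = session$role_map,
                 moves_per_min_arm1 = movements_per_minute(ev1, total_s),
                 moves_per_min_arm2 = movements_per_minute(ev2, total_s),
                 mmr = median_magnitude_ratio(ratios, min_active_epochs),
                 n_active_epochs = length(ratios),
                 n_unilateral_epochs = sum(xor(epochs$active_arm1,
                                               epochs$active_arm2)),
                 alt_use_ratio = alternative_laterality(epochs, "use_ratio"),
                 alt_laterality_index =
                   alternative_laterality(epochs, "laterality_index"),
                 total_task_s = total_s,
                 events_arm1 = ev1, events_arm2 = ev2,
                 epochs = epochs,
                 config = config,
                 config_fingerprint = config_fingerprint(config)),
            class = "gesture_metrics")
}

config_fingerprint <- function(config) {
  paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                              character(1)),
        sep = "=", collapse = ";")
}

#' @export
print.gesture_metrics <- function(x, ...) {
  cat(sprintf("gesture_metrics: %s\n", x$participant_id))
  cat(sprintf("  movements/min: preferred %.2f, nonpreferred %.2f (over %.0f s)\n",
              x$moves_per_min_arm1, x$moves_per_min_arm2, x$total_task_s))
  if (is.na(x$mmr)) {
    cat("  MMR: missing -", attr(x$mmr, "reason"), "\n")
  } else {
    cat(sprintf("  MMR: %.3f over %d active epochs (%d unilateral)\n",
                x$mmr, x$n_active_epochs, x$n_unilateral_epochs))
  }
  cat(sprintf("  use ratio %.3f, laterality index %.3f\n",
              x$alt_use_ratio, x$alt_laterality_index))
  invisible(x)
}

#' @export
plot.gesture_metrics <- function(x, ...) {
  ep <- x$epochs
  graphics::plot(ep$t_start_s, ep$mag_arm1, type = "h", col = "grey40",
                 xlab = "time (s)", ylab = "epoch magnitude (g)",
                 main = x$participant_id, ...)
  graphics::points(ep$t_start_s, -ep$mag_arm2, type = "h", col = "firebrick")
  graphics::abline(h = 0)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("grey40", "firebrick"),
                   legend = c("preferred (up)", "nonpreferred (down)"))
  invisible(x)
}
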