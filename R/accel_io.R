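#' Construct a wrist accelerometer recording
#'
#' An `accel_recording` holds one wrist's tri-axial acceleration time series
#' in units of g, together with its sampling rate, start time, and the arm it
#' was worn on.
#'
#' @param participant_id Participant identifier (single string).
#' @param arm_side `"left"` or `"right"`.
#' @param arm_role One of `"intact"`, `"prosthesis"`, `"dominant"`,
#'   `"nondominant"`.
#' @param fs Sampling rate in Hz (> 0).
#' @param data Numeric matrix with columns `ax`, `ay`, `az` in g; one row per
#'   sample.
#' @param t0 Recording start time in seconds relative to session start.
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(participant_id, arm_side, arm_role, fs, data,
                            t0 = 0) {
  arm_side <- match.arg(arm_side, c("left", "right"))
  arm_role <- match.arg(arm_role,
                        c("intact", "prosthesis", "dominant", "nondominant"))
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("recording data must have exactly 3 axis columns")
  if (nrow(data) < 1L)
    stop("recording must contain at least one sample")
  if (anyNA(data))
    stop("recording contains NaN/NA samples after validation")
  colnames(data) <- c("ax", "ay", "az")
  structure(list(participant_id = participant_id,
                 arm_side = arm_side,
                 arm_role = arm_role,
                 fs = fs, t0 = t0, data = data),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("accel_recording: %s, %s arm (%s)\n",
              x$participant_id, x$arm_side, x$arm_role))
  cat(sprintf("  %d samples at %.6g Hz (%.1f s), t0 = %.3f s\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs, x$t0))
  invisible(x)
}

rec_duration <- function(rec) nrow(rec$data) / rec$fs
rec_end <- function(rec) rec$t0 + rec_duration(rec)

#' Describe a raw-accelerometry CSV dialect
#'
#' The canonical raw dialect is a headered CSV with columns
#' `time_s, ax_g, ay_g, az_g`. Units may instead be metres per second squared,
#' in which case values are divided by 9.80665 on read. The sampling rate is
#' either declared or inferred from the median time step; relative jitter in
#' the time column beyond `jitter_tol` is rejected.
#'
#' @param units `"g"` or `"ms2"` (metres per second squared).
#' @param fs Declared sampling rate in Hz, or `NULL` to infer from the time
#'   column.
#' @param jitter_tol Maximum allowed relative deviation of any time step from
#'   the median step (default 0.01).
#' @param na_action `"reject"` (default) or `"interpolate"`: short gaps of
#'   missing samples up to `max_gap_s` are linearly interpolated when
#'   `"interpolate"`.
#' @param max_gap_s Longest NA gap, in seconds, that may be interpolated.
#' @return A list of class `accel_dialect`.
#' @export
accel_dialect <- function(units = c("g", "ms2"), fs = NULL,
                          jitter_tol = 0.01,
                          na_action = c("reject", "interpolate"),
                          max_gap_s = 0.2) {
  structure(list(units = match.arg(units), fs = fs,
                 jitter_tol = jitter_tol,
                 na_action = match.arg(na_action),
                 max_gap_s = max_gap_s),
            class = "accel_dialect")
}

STANDARD_GRAVITY <- 9.80665

#' Read one wrist recording from CSV
#'
#' @param path Path to a CSV in the dialect's layout
#'   (`time_s, ax_g, ay_g, az_g`).
#' @param participant_id,arm_side,arm_role Metadata attached to the recording
#'   (not stored in the raw file).
#' @param dialect An [accel_dialect()].
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, participant_id, arm_side, arm_role,
                           dialect = accel_dialect()) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  tm <- df$time_s
  if (length(tm) < 1L) stop("empty recording: ", path)
  if (length(tm) > 1L) {
    dt <- diff(tm)
    if (any(dt <= 0))
      stop("non-monotone time column in ", path, " at row ",
           which(dt <= 0)[1L] + 1L)
    med <- stats::median(dt)
    bad <- which(abs(dt - med) > dialect$jitter_tol * med)
    if (length(bad))
      stop("inconsistent sampling in ", path, " at row ", bad[1L] + 1L,
           sprintf(" (step %.6g s vs median %.6g s)", dt[bad[1L]], med))
    fs <- if (is.null(dialect$fs)) 1 / med else dialect$fs
  } else {
    if (is.null(dialect$fs))
      stop("single-sample file needs a declared fs: ", path)
    fs <- dialect$fs
  }
  dat <- as.matrix(df[, c("ax_g", "ay_g", "az_g")])
  if (dialect$units == "ms2") dat <- dat / STANDARD_GRAVITY
  for (j in 1:3) if (all(is.na(dat[, j])))
    stop("all-NaN axis ", c("x", "y", "z")[j], " in ", path)
  if (anyNA(dat)) {
    if (dialect$na_action == "reject") {
      stop("NaN samples in ", path, " at row ",
           which(rowSums(is.na(dat)) > 0)[1L],
           " (na_action = 'reject')")
    }
    dat <- interpolate_gaps(dat, fs, dialect$max_gap_s, path)
  }
  accel_recording(participant_id, arm_side, arm_role, fs, dat, t0 = tm[1L])
}

# Linear interpolation of NA runs no longer than max_gap_s; longer runs fail.
interpolate_gaps <- function(dat, fs, max_gap_s, path) {
  max_run <- max(1L, floor(max_gap_s * fs))
  for (j in 1:3) {
    na <- is.na(dat[, j])
    if (!any(na)) next
    r <- rle(na)
    runs <- r$lengths[r$values]
    if (any(runs > max_run) || na[1L] || na[length(na)])
      stop("NA gap too long (or at boundary) to interpolate in ", path)
    dat[, j] <- stats::approx(which(!na), dat[!na, j], xout = seq_len(nrow(dat)))$y
  }
  dat
}

#' Write a recording in the canonical raw CSV dialect
#'
#' @param rec An [accel_recording()].
#' @param path Output CSV path.
#' @param digits Significant digits used for formatting (default 6).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 6) {
  tm <- rec$t0 + (seq_len(nrow(rec$data)) - 1L) / rec$fs
  df <- data.frame(time_s = signif(tm, digits + 4),
                   ax_g = signif(rec$data[, 1], digits),
                   ay_g = signif(rec$data[, 2], digits),
                   az_g = signif(rec$data[, 3], digits))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Task windows
#'
#' @param label Character vector of window labels (e.g. `"paired_objects"`,
#'   `"storytelling"`).
#' @param start_s,end_s Window bounds in seconds relative to session start;
#'   windows are half-open `[start, end)` and must not overlap.
#' @return A `data.frame` of class `task_windows`.
#' @export
task_windows <- function(label, start_s, end_s) {
  stopifnot(length(label) == length(start_s),
            length(start_s) == length(end_s))
  if (any(end_s <= start_s)) stop("each window needs end_s > start_s")
  if (length(start_s) > 1L) {
    o <- order(start_s)
    if (any(start_s[o][-1L] < end_s[o][-length(o)]))
      stop("task windows overlap")
  }
  structure(data.frame(label = as.character(label),
                       start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s)),
            class = c("task_windows", "data.frame"))
}

#' Assemble a bimanual recording session
#'
#' Pairs the two wrists' recordings, checks that they cover opposite sides,
#' and clips every task window to the temporal intersection of the two
#' recordings (clipping is reported via a message).
#'
#' @param rec_a,rec_b [accel_recording()]s of the same participant, distinct
#'   sides.
#' @param windows A [task_windows()] object (or data.frame with the same
#'   columns).
#' @return An object of class `bimanual_session` with elements
#'   `recording_a`, `recording_b` (preferred arm first: intact or dominant),
#'   `windows`, and `role_map` (named character, side -> role).
#' @export
build_session <- function(rec_a, rec_b, windows) {
  stopifnot(inherits(rec_a, "accel_recording"),
            inherits(rec_b, "accel_recording"))
  if (rec_a$participant_id != rec_b$participant_id)
    stop("recordings belong to different participants")
  if (rec_a$arm_side == rec_b$arm_side)
    stop("both recordings cover the ", rec_a$arm_side, " side")
  roles <- sort(c(rec_a$arm_role, rec_b$arm_role))
  if (!identical(roles, c("intact", "prosthesis")) &&
      !identical(roles, c("dominant", "nondominant")))
    stop("arm roles must pair intact/prosthesis or dominant/nondominant, got ",
         paste(roles, collapse = "/"))
  # preferred arm (intact or dominant) is always recording_a
  if (rec_a$arm_role %in% c("prosthesis", "nondominant")) {
    tmp <- rec_a; rec_a <- rec_b; rec_b <- tmp
  }
  lo <- max(rec_a$t0, rec_b$t0)
  hi <- min(rec_end(rec_a), rec_end(rec_b))
  if (hi <= lo) stop("recordings have zero temporal overlap")
  windows <- as.data.frame(windows)
  clipped <- windows
  clipped$start_s <- pmax(windows$start_s, lo)
  clipped$end_s <- pmin(windows$end_s, hi)
  keep <- clipped$end_s > clipped$start_s
  if (any(clipped$start_s[keep] != windows$start_s[keep] |
          clipped$end_s[keep] != windows$end_s[keep]))
    message("task windows clipped to recording overlap [",
            signif(lo, 6), ", ", signif(hi, 6), ") s")
  if (!any(keep)) stop("no task window overlaps both recordings")
  clipped <- clipped[keep, , drop = FALSE]
  rownames(clipped) <- NULL
  role_map <- stats::setNames(c(rec_a$arm_role, rec_b$arm_role),
                              c(rec_a$arm_side, rec_b$arm_side))
  structure(list(participant_id = rec_a$participant_id,
                 recording_a = rec_a, recording_b = rec_b,
                 windows = clipped, role_map = role_map),
            class = "bimanual_session")
}

#' @export
print.bimanual_session <- function(x, ...) {
  cat(sprintf("bimanual_session: %s\n", x$participant_id))
  cat(sprintf("  arm A: %s (%s), arm B: %s (%s)\n",
              x$recording_a$arm_side, x$recording_a$arm_role,
              x$recording_b$arm_side, x$recording_b$arm_role))
  cat(sprintf("  %d task window(s), %.1f s total\n", nrow(x$windows),
              sum(x$windows$end_s - x$windows$start_s)))
  invisible(x)
}

#' Write an epoch series to CSV
#'
#' Columns: `epoch_index, t_start_s, mag_arm1_g, mag_arm2_g, active_arm1,
#' active_arm2`. `read_epochs()` restores the series so that
#' `read_epochs(write_epochs(x))` equals `x` up to the declared formatting
#' precision.
#'
#' @param epochs An `epoch_series` (see [epoch_magnitudes()]).
#' @param path Output CSV path.
#' @param digits Significant digits for magnitudes (default 6).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, digits = 6) {
  df <- data.frame(epoch_index = epochs$epoch_index,
                   t_start_s = signif(epochs$t_start_s, digits + 4),
                   mag_arm1_g = signif(epochs$mag_arm1, digits),
                   mag_arm2_g = signif(epochs$mag_arm2, digits),
                   active_arm1 = as.integer(epochs$active_arm1),
                   active_arm2 = as.integer(epochs$active_arm2))
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write epoch file: ", path)
  invisible(path)
}

#' Read an epoch series written by [write_epochs()]
#'
#' @param path Epoch CSV path.
#' @param participant_id,epoch_len_s,role_map,activity_threshold_g Metadata to
#'   attach (not stored in the CSV body).
#' @return An `epoch_series`.
#' @export
read_epochs <- function(path, participant_id = NA_character_,
                        epoch_len_s = 1, role_map = NULL,
                        activity_threshold_g = 0.01) {
  if (!file.exists(path)) stop("epoch file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("epoch_index", "t_start_s", "mag_arm1_g", "mag_arm2_g",
            "active_arm1", "active_arm2")
  if (!all(need %in% names(df)))
    stop("missing epoch columns: ", paste(setdiff(need, names(df)),
                                          collapse = ", "))
  epoch_series(participant_id = participant_id,
               epoch_index = df$epoch_index, t_start_s = df$t_start_s,
               mag_arm1 = df$mag_arm1_g, mag_arm2 = df$mag_arm2_g,
               active_arm1 = as.logical(df$active_arm1),
               active_arm2 = as.logical(df$active_arm2),
               epoch_len_s = epoch_len_s, role_map = role_map,
               activity_threshold_g = activity_threshold_g)
}

#' Construct an epoch series
#'
#' Per-second (by default) aligned movement magnitudes for the two arms.
#' Arm 1 is always the preferred arm (intact or dominant); arm 2 the
#' nonpreferred arm (prosthesis or nondominant).
#'
#' @param participant_id Participant identifier.
#' @param epoch_index Integer epoch indices.
#' @param t_start_s Epoch start times in seconds.
#' @param mag_arm1,mag_arm2 Mean gravity-removed magnitudes per epoch, in g.
#' @param active_arm1,active_arm2 Logical activity flags per epoch.
#' @param epoch_len_s Epoch length in seconds.
#' @param role_map Named character vector (side -> role), carried from the
#'   session.
#' @param activity_threshold_g Threshold defining the active flags.
#' @return A `data.frame` of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, epoch_index, t_start_s,
                         mag_arm1, mag_arm2, active_arm1, active_arm2,
                         epoch_len_s = 1, role_map = NULL,
                         activity_threshold_g = 0.01) {
  n <- length(epoch_index)
  stopifnot(length(t_start_s) == n, length(mag_arm1) == n,
            length(mag_arm2) == n, length(active_arm1) == n,
            length(active_arm2) == n)
  if (n > 0 && (any(mag_arm1 < 0) || any(mag_arm2 < 0)))
    stop("epoch magnitudes must be non-negative")
  out <- data.frame(epoch_index = as.integer(epoch_index),
                    t_start_s = as.numeric(t_start_s),
                    mag_arm1 = as.numeric(mag_arm1),
                    mag_arm2 = as.numeric(mag_arm2),
                    active_arm1 = as.logical(active_arm1),
                    active_arm2 = as.logical(active_arm2))
  structure(out,
            class = c("epoch_series", "data.frame"),
            participant_id = participant_id,
            epoch_len_s = epoch_len_s,
            role_map = role_map,
            activity_threshold_g = activity_threshold_g)
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("epoch_series: %s, %d epochs of %.3g s\n",
              attr(x, "participant_id"), nrow(x), attr(x, "epoch_len_s")))
  cat(sprintf("  active epochs: arm1 %d, arm2 %d, either %d (threshold %.3g g)\n",
              sum(x$active_arm1), sum(x$active_arm2),
              sum(x$active_arm1 | x$active_arm2),
              attr(x, "activity_threshold_g")))
  NextMethod()
}
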