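#' Euclidean sample magnitude
#'
#' Vector magnitude of a tri-axial acceleration sample, the scalar
#' movement-intensity signal used throughout.
#'
#' @param ax,ay,az Numeric vectors of axis accelerations (g).
#' @return `sqrt(ax^2 + ay^2 + az^2)`, elementwise.
#' @export
sample_magnitude <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop("sample_magnitude requires finite inputs")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Remove the gravity component of a recording
#'
#' Two methods are offered. `"highpass"` (default) applies a zero-phase
#' (forward-backward) 4th-order Butterworth high-pass per axis, after
#' reflection padding to suppress edge transients, and then takes the vector
#' magnitude. `"magnitude_minus_1g"` subtracts 1 g from the vector magnitude
#' and takes the absolute value; it needs no filter but conflates orientation
#' change with movement.
#'
#' @param rec An [accel_recording()].
#' @param method `"highpass"` or `"magnitude_minus_1g"`.
#' @param cutoff_hz High-pass cutoff in Hz (default 0.25). Must be below the
#'   Nyquist frequency `fs / 2`.
#' @param order Butterworth order (default 4; effective order doubles with
#'   the zero-phase pass).
#' @return A `filtered_signal`: list with `participant_id`, `arm_side`,
#'   `arm_role`, `fs`, `t0`, and `mag`, the per-sample gravity-removed
#'   magnitude in g.
#' @export
remove_gravity <- function(rec, method = c("highpass", "magnitude_minus_1g"),
                           cutoff_hz = 0.25, order = 4) {
  stopifnot(inherits(rec, "accel_recording"))
  method <- match.arg(method)
  if (method == "highpass") {
    if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2)
      stop(sprintf("cutoff %.3g Hz not below Nyquist %.3g Hz",
                   cutoff_hz, rec$fs / 2))
    filt <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
    f <- apply(rec$data, 2, function(x)
      zero_phase_filter(filt, x, rec$fs, cutoff_hz))
    mag <- sample_magnitude(f[, 1], f[, 2], f[, 3])
  } else {
    mag <- abs(sample_magnitude(rec$data[, 1], rec$data[, 2],
                                rec$data[, 3]) - 1)
  }
  structure(list(participant_id = rec$participant_id,
                 arm_side = rec$arm_side, arm_role = rec$arm_role,
                 fs = rec$fs, t0 = rec$t0, mag = mag,
                 method = method, cutoff_hz = cutoff_hz),
            class = "filtered_signal")
}

# filtfilt with reflection padding: ~3 filter time constants on each side,
# capped at the signal length.
zero_phase_filter <- function(filt, x, fs, cutoff_hz) {
  n <- length(x)
  if (n < 4L) return(x - mean(x))
  npad <- min(round(3 / cutoff_hz * fs), n - 1L)
  left <- 2 * x[1L] - rev(x[2L:(npad + 1L)])
  right <- 2 * x[n] - rev(x[(n - npad):(n - 1L)])
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(npad + 1L):(npad + n)]
}

#' Aggregate a session into per-epoch movement magnitudes
#'
#' For each task window, cuts time into consecutive half-open epochs
#' `[start, start + epoch_len_s)` and averages each arm's gravity-removed
#' sample magnitudes within the epoch. A trailing partial epoch is dropped.
#' An arm is flagged active in an epoch when its mean magnitude reaches
#' `activity_threshold_g`.
#'
#' @param session A [build_session()] result.
#' @param epoch_len_s Epoch length in seconds (default 1, per-second epochs).
#' @param activity_threshold_g Activity threshold in g (default 0.01).
#' @param method,cutoff_hz Passed to [remove_gravity()].
#' @return An [epoch_series()]; arm 1 is the preferred (intact/dominant) arm.
#' @export
epoch_magnitudes <- function(session, epoch_len_s = 1,
                             activity_threshold_g = 0.01,
                             method = "highpass", cutoff_hz = 0.25) {
  stopifnot(inherits(session, "bimanual_session"), epoch_len_s > 0)
  f1 <- remove_gravity(session$recording_a, method, cutoff_hz)
  f2 <- remove_gravity(session$recording_b, method, cutoff_hz)
  idx <- 0L
  rows <- vector("list", nrow(session$windows))
  for (w in seq_len(nrow(session$windows))) {
    ws <- session$windows$start_s[w]
    we <- session$windows$end_s[w]
    if (we - ws < epoch_len_s)
      stop(sprintf("window '%s' shorter than one epoch (%.3g s < %.3g s)",
                   session$windows$label[w], we - ws, epoch_len_s))
    n_ep <- floor((we - ws) / epoch_len_s + 1e-9)
    starts <- ws + (seq_len(n_ep) - 1L) * epoch_len_s
    m1 <- epoch_means(f1, starts, epoch_len_s)
    m2 <- epoch_means(f2, starts, epoch_len_s)
    rows[[w]] <- data.frame(epoch_index = idx + seq_len(n_ep),
                            t_start_s = starts, mag_arm1 = m1, mag_arm2 = m2)
    idx <- idx + n_ep
  }
  df <- do.call(rbind, rows)
  epoch_series(participant_id = session$participant_id,
               epoch_index = df$epoch_index, t_start_s = df$t_start_s,
               mag_arm1 = df$mag_arm1, mag_arm2 = df$mag_arm2,
               active_arm1 = df$mag_arm1 >= activity_threshold_g,
               active_arm2 = df$mag_arm2 >= activity_threshold_g,
               epoch_len_s = epoch_len_s, role_map = session$role_map,
               activity_threshold_g = activity_threshold_g)
}

# Mean of per-sample magnitudes whose timestamps fall in [start, start+len).
epoch_means <- function(fsig, starts, len) {
  vapply(starts, function(s) {
    k0 <- ceiling((s - fsig$t0) * fsig$fs - 1e-9)
    k1 <- ceiling((s + len - fsig$t0) * fsig$fs - 1e-9) - 1
    k0 <- max(k0, 0)
    k1 <- min(k1, length(fsig$mag) - 1)
    if (k1 < k0) return(0)
    mean(fsig$mag[(k0 + 1L):(k1 + 1L)])
  }, numeric(1))
}
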