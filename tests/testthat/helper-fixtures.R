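# Fixture builders and independent oracles used across the suite.

# Recording built directly from axis vectors (g).
make_recording <- function(ax, ay, az, fs = 50, id = "p01",
                           side = "left", role = "intact", t0 = 0) {
  accel_recording(id, side, role, fs, cbind(ax, ay, az), t0 = t0)
}

# Raw CSV in the canonical dialect.
write_raw_csv <- function(path, time_s, ax, ay, az) {
  utils::write.csv(data.frame(time_s = time_s, ax_g = ax, ay_g = ay,
                              az_g = az),
                   path, row.names = FALSE)
  path
}

# Epoch series straight from magnitude vectors.
make_epochs <- function(m1, m2, threshold = 0.01, id = "p01", cap_len = 1) {
  epoch_series(participant_id = id, epoch_index = seq_along(m1),
               t_start_s = seq_along(m1) - 1, mag_arm1 = m1, mag_arm2 = m2,
               active_arm1 = m1 >= threshold, active_arm2 = m2 >= threshold,
               epoch_len_s = cap_len, activity_threshold_g = threshold)
}

# Swap the two arms of an epoch series (role reversal).
swap_epochs <- function(ep) {
  epoch_series(participant_id = attr(ep, "participant_id"),
               epoch_index = ep$epoch_index, t_start_s = ep$t_start_s,
               mag_arm1 = ep$mag_arm2, mag_arm2 = ep$mag_arm1,
               active_arm1 = ep$active_arm2, active_arm2 = ep$active_arm1,
               epoch_len_s = attr(ep, "epoch_len_s"),
               activity_threshold_g = attr(ep, "activity_threshold_g"))
}

# Enumeration oracle for the Mann-Whitney U: null distribution of U over all
# choose(n1+n2, n1) group labelings of the pooled sample.
enum_mwu <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_all <- apply(utils::combn(n, n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(u = u_obs, p = p)
}

# Brute-force Spearman through hand-built mid-ranks and the Pearson formula.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Independent JZS oracle: trapezoid quadrature on a fine grid after the
# substitution g = u / (1 - u), u in (0, 1).
trapezoid_bf10 <- function(t, n, r = sqrt(2) / 2, m = 40000) {
  nu <- n - 1
  u <- seq(1e-7, 1 - 1e-7, length.out = m)
  g <- u / (1 - u)
  f <- (1 + n * g * r^2)^(-0.5) *
    (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
    (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)) / (1 - u)^2
  num <- sum((f[-1] + f[-m]) / 2 * diff(u))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Simulated session shared by several tests.
quick_session <- function(k = 1, seed = 1, duration_s = 120, ...) {
  simulate_session(signal_sim_params(duration_s = duration_s,
                                     laterality_k = k, seed = seed, ...))
}
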