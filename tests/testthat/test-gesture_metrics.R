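test_that("movement detection segments suprathreshold runs with gap merging", {
  fs <- 100
  expect_equal(nrow(detect_movements(rep(0, 1000), fs = fs)), 0)

  # three 1 s bursts at 0.5 g separated by 5 s of quiet
  mag <- rep(0, 18 * fs)
  for (s in c(1, 7, 13)) mag[(s * fs + 1):((s + 1) * fs)] <- 0.5
  ev <- detect_movements(mag, threshold_g = 0.05, min_dur_s = 0.25,
                         merge_gap_s = 0.25, fs = fs)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$start_s, c(1, 7, 13), tolerance = 1e-9)
  expect_equal(ev$peak_mag_g, rep(0.5, 3))

  # two bursts separated by a 0.1 s dip merge into one event
  mag2 <- c(rep(0, 100), rep(0.5, 50), rep(0, 10), rep(0.5, 50), rep(0, 100))
  ev2 <- detect_movements(mag2, threshold_g = 0.05, min_dur_s = 0.25,
                          merge_gap_s = 0.25, fs = fs)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$end_s - ev2$start_s, 1.1, tolerance = 1e-9)

  # too-short blips are discarded
  mag3 <- c(rep(0, 100), rep(0.5, 10), rep(0, 100))
  expect_equal(nrow(detect_movements(mag3, threshold_g = 0.05,
                                     min_dur_s = 0.25, merge_gap_s = 0.25,
                                     fs = fs)), 0)
})

test_that("movement rate is a straight count per minute", {
  ev <- data.frame(arm_role = "intact", start_s = 1:12, end_s = 1:12 + 0.5,
                   peak_mag_g = 0.5, mean_mag_g = 0.3)
  expect_equal(movements_per_minute(ev, 240), 3.0)
  expect_equal(movements_per_minute(ev[0, ], 240), 0.0)
  expect_error(movements_per_minute(ev, 0), "positive")
  set.seed(11)
  for (i in 1:5) {
    n <- rpois(1, 20); dur <- runif(1, 60, 600)
    evr <- data.frame(start_s = sort(runif(n, 0, dur)))
    expect_equal(movements_per_minute(evr, dur), 60 * n / dur)
  }
})

test_that("log magnitude ratios follow the sign, cap and exclusion rules", {
  ep <- make_epochs(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(magnitude_ratio_series(ep), c(0, 0, 0))

  ep2 <- make_epochs(c(0.1, 0.2), c(0.2, 0.4))
  expect_equal(magnitude_ratio_series(ep2), rep(log(2), 2),
               tolerance = 1e-12)

  # unilateral epochs get the cap with the arm-appropriate sign
  ep3 <- make_epochs(c(0.2, 0, 0.005), c(0, 0.2, 0.005))
  expect_equal(magnitude_ratio_series(ep3, cap = 7)[1:2], c(-7, 7))
  # both-inactive epochs are excluded entirely
  expect_length(magnitude_ratio_series(ep3, cap = 7), 2)

  # extreme bilateral ratios clamp to the same bounds
  ep4 <- make_epochs(c(1, 1e-9), c(1e-9, 1), threshold = 1e-10)
  expect_equal(magnitude_ratio_series(ep4, cap = 7), c(-7, 7))
})

test_that("the MMR is the sample median with a minimum-evidence flag", {
  expect_equal(median_magnitude_ratio(rep(0, 20)), 0)
  expect_equal(median_magnitude_ratio(c(-1, -0.5, 0.2),
                                      min_active_epochs = 3), -0.5)
  set.seed(3)
  for (i in 1:20) {
    r <- rnorm(sample(10:99, 1))
    s <- sort(r); n <- length(s)
    brute <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_identical(median_magnitude_ratio(r), brute)
  }
  flagged <- median_magnitude_ratio(rnorm(5))
  expect_true(is.na(flagged))
  expect_match(attr(flagged, "reason"), "active epochs")
})

test_that("alternative laterality indices behave at the symmetric and degenerate poles", {
  ep <- make_epochs(c(0.2, 0.3), c(0.2, 0.3))
  expect_equal(alternative_laterality(ep, "use_ratio"), 1)
  expect_equal(alternative_laterality(ep, "laterality_index"), 0)
  ep2 <- make_epochs(c(0.2, 0.3), c(0, 0))
  expect_equal(alternative_laterality(ep2, "use_ratio"), 0)
  expect_equal(alternative_laterality(ep2, "laterality_index"), -1)
  set.seed(4)
  for (i in 1:10) {
    ep3 <- make_epochs(abs(rnorm(30, 0.1, 0.1)), abs(rnorm(30, 0.1, 0.1)))
    li <- alternative_laterality(ep3, "laterality_index")
    expect_gte(li, -1); expect_lte(li, 1)
  }
  epz <- make_epochs(c(0, 0), c(0.1, 0.1))
  expect_true(is.na(alternative_laterality(epz, "use_ratio")))
})

test_that("laterality metrics are antisymmetric under arm-role swapping", {
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    ep <- make_epochs(abs(rnorm(n, 0.1, 0.12)), abs(rnorm(n, 0.05, 0.08)))
    sw <- swap_epochs(ep)
    r <- magnitude_ratio_series(ep)
    expect_identical(median_magnitude_ratio(sw |> magnitude_ratio_series()),
                     -median_magnitude_ratio(r))
    expect_equal(alternative_laterality(sw, "laterality_index"),
                 -alternative_laterality(ep, "laterality_index"),
                 tolerance = 1e-15)
    ur <- alternative_laterality(ep, "use_ratio")
    if (!is.na(ur) && ur > 0)
      expect_equal(alternative_laterality(sw, "use_ratio"), 1 / ur,
                   tolerance = 1e-15)
  }
})

test_that("the MMR is scale invariant and monotone in the nonpreferred magnitudes", {
  set.seed(6)
  m1 <- abs(rnorm(80, 0.1, 0.1)); m2 <- abs(rnorm(80, 0.08, 0.1))
  ep <- make_epochs(m1, m2, threshold = 0.01)
  ep_scaled <- make_epochs(3 * m1, 3 * m2, threshold = 3 * 0.01)
  expect_lt(abs(median_magnitude_ratio(magnitude_ratio_series(ep)) -
                  median_magnitude_ratio(magnitude_ratio_series(ep_scaled))),
            1e-9)
  mmr0 <- median_magnitude_ratio(magnitude_ratio_series(ep))
  for (f in c(1.2, 2, 5)) {
    ep_up <- make_epochs(m1, f * m2, threshold = 0.01)
    expect_gte(median_magnitude_ratio(magnitude_ratio_series(ep_up)), mmr0)
  }
  expect_lte(max(abs(magnitude_ratio_series(ep, cap = 4))), 4)
})

test_that("simulated sessions recover the injected amplitude ratio", {
  mm <- vapply(1:50, function(s) {
    sim <- quick_session(k = 0.5, seed = s, duration_s = 300)
    compute_gesture_metrics(sim$session)$mmr
  }, numeric(1))
  expect_lt(abs(median(mm) - log(0.5)), 0.05)
  expect_gt(min(vapply(1:5, function(s) {
    sim <- simulate_session(signal_sim_params(gesture_rate_per_min = 30,
                                              seed = s))
    compute_gesture_metrics(sim$session)$n_active_epochs
  }, numeric(1))), 100)
})

test_that("a quiet session yields flagged-missing metrics without crashing", {
  sim <- simulate_session(signal_sim_params(duration_s = 10,
                                            gesture_rate_per_min = 0,
                                            noise_sd_g = 0, seed = 1))
  gm <- compute_gesture_metrics(sim$session)
  expect_true(is.na(gm$mmr))
  expect_equal(gm$moves_per_min_arm1, 0)
  expect_equal(gm$moves_per_min_arm2, 0)
  expect_true(is.na(gm$alt_use_ratio))
  expect_output(print(gm), "missing")
})
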