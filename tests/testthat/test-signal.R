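make_trace <- function(force, fs = 1000) {
  force_trace((seq_along(force) - 1) / fs, force, sample_rate = fs)
}

test_that("bodyweight estimation uses the quiet window and flags instability", {
  tr <- make_trace(rep(700, 1500))
  bw <- estimate_bodyweight(tr, window_s = 1)
  expect_equal(bw$bodyweight, 700)
  expect_equal(bw$body_mass, 700 / 9.81, tolerance = 1e-12)
  # zero-mean noise: the mean stays within 3 standard errors
  set.seed(1)
  n <- 1000
  tr2 <- make_trace(700 + rnorm(n + 500, 0, 2))
  bw2 <- estimate_bodyweight(tr2, window_s = 1)
  expect_lt(abs(bw2$bodyweight - 700), 3 * 2 / sqrt(n))
  # a ramp in the window is not quiet standing
  expect_error(estimate_bodyweight(make_trace(seq(700, 900, length.out = 1500)), 1),
               "no stable quiet standing")
})

test_that("impulse-momentum integration matches closed forms and a trapezoid oracle", {
  # force identically bodyweight: nothing moves
  tr <- make_trace(rep(70 * 9.81, 1200))
  kin <- compute_kinematics(tr, 70)
  expect_equal(max(abs(kin$velocity)), 0)
  expect_equal(max(abs(kin$displacement)), 0)
  # constant 2 m/s^2 net acceleration held 0.1 s from rest: v = 0.2 m/s
  tr2 <- make_trace(rep(1 * (9.81 + 2), 1001))
  kin2 <- compute_kinematics(tr2, 1)
  expect_equal(kin2$velocity[101], 2 * 0.1, tolerance = 1e-12)
  # 7-sample toy trace against the loop oracle
  f <- c(9.81, 10.81, 11.81, 10.81, 9.81, 9.81, 9.81)
  tr3 <- force_trace((0:6) / 1000, f, sample_rate = 1000)
  kin3 <- compute_kinematics(tr3, 1)
  expect_equal(kin3$velocity, cumtrapz_loop((0:6) / 1000, f / 1 - 9.81),
               tolerance = 1e-12)
  expect_equal(kin3$power, f * kin3$velocity, tolerance = 1e-12)
})

test_that("takeoff detection finds the first sub-threshold sample after the peak", {
  a <- athlete_params("A01")
  tr <- simulate_trace(a, 0, seed = 5)
  truth <- attr(tr, "truth")
  expect_lte(abs(detect_takeoff(tr) - truth$takeoff_index), 2)
  # quiet trace: no flight phase
  expect_error(detect_takeoff(make_trace(700 + sin(1:1500) * 4)), "no flight")
  # threshold above the propulsion peak is degenerate
  expect_error(detect_takeoff(tr, threshold = max(tr$force) * 1.1),
               "no flight|threshold")
})

test_that("concentric extraction anchors on the velocity zero-crossing", {
  a <- athlete_params("A02", body_mass = 82)
  tr <- simulate_trace(a, 0.05, seed = 9)
  truth <- attr(tr, "truth")
  seg <- extract_concentric(tr)
  expect_lte(abs(seg$onset_index - truth$onset_index), 2)
  expect_false(seg$fallback)
  expect_lte(abs(seg$velocity[1]), 0.02)
  expect_true(all(seg$velocity[-1] > 0))
  # quiet standing only: propagated takeoff error
  expect_error(extract_concentric(make_trace(rep(700, 1500))), "no flight")
  # no countermovement at all: fallback path, flagged
  tr_nd <- simulate_trace(a, 0, dip_amplitude = 0, seed = 9)
  seg_nd <- extract_concentric(tr_nd)
  expect_true(seg_nd$fallback)
})

test_that("scalar features match a hand-computed oracle and tie-break early", {
  # tabulated toy segment: mass 70 kg, BW 686.7 N
  seg <- structure(list(
    time = (0:4) / 100,
    force = c(700, 900, 1200, 1200, 800),
    velocity = c(0, 0.3, 0.9, 1.6, 2.0),
    power = c(700, 900, 1200, 1200, 800) * c(0, 0.3, 0.9, 1.6, 2.0),
    bodyweight = 686.7, body_mass = 70,
    onset_index = 101, takeoff_index = 106, sample_rate = 100,
    fallback = FALSE, meta = list()), class = "concentric_segment")
  ft <- extract_features(seg)
  expect_equal(ft$rel_peak_force, 1200 / 686.7)
  expect_equal(ft$rel_peak_power, 1200 * 1.6 / 70)
  expect_equal(ft$t_con, 0.05)
  expect_equal(ft$t_peak_force, 0.02)  # earliest of the tied maxima
  # peak at the final sample: t_peak_force equals the last time stamp
  seg$force <- c(700, 800, 900, 1000, 1100)
  ft2 <- extract_features(seg)
  expect_equal(ft2$t_peak_force, 0.04)
})

test_that("propulsion peak counting respects prominence", {
  a <- athlete_params("A03")
  seg1 <- extract_concentric(simulate_trace(a, 0, double_peak = FALSE, seed = 3))
  expect_equal(count_propulsion_peaks(seg1), 1)
  seg2 <- extract_concentric(simulate_trace(a, 0, double_peak = TRUE, seed = 3))
  expect_equal(count_propulsion_peaks(seg2), 2)
  expect_equal(count_propulsion_peaks(seg2, prominence = 5), 0)
})

test_that("jump height from takeoff velocity agrees with flight time within 2%", {
  a <- athlete_params("A04", body_mass = 70)
  for (seed in 1:5) {
    tr <- simulate_trace(a, decrement = 0.04 * (seed - 1), seed = seed)
    truth <- attr(tr, "truth")
    h_v <- truth$v_takeoff^2 / (2 * 9.81)
    h_t <- 9.81 * truth$flight_time^2 / 8
    expect_lt(abs(h_v - h_t) / h_v, 0.02)
  }
})

test_that("features converge under sample-rate doubling and shift invariance", {
  a <- athlete_params("A05")
  f600 <- extract_features(extract_concentric(simulate_trace(a, 0.05, seed = 8)))
  f1200 <- extract_features(extract_concentric(
    simulate_trace(a, 0.05, sample_rate = 1200, seed = 8)))
  for (k in c("rel_peak_force", "rel_peak_power", "t_con")) {
    expect_lt(abs(f1200[[k]] - f600[[k]]) / abs(f600[[k]]), 0.005)
  }
  # the discrete argmax of a smooth peak carries +-dt/2 quantisation, so the
  # peak time is compared at the coarse grid's sample resolution
  expect_lt(abs(f1200$t_peak_force - f600$t_peak_force), 1 / 600)
  # adding a constant time offset changes nothing
  tr <- simulate_trace(a, 0.05, seed = 8)
  tr_off <- force_trace(tr$time + 3.7, tr$force, sample_rate = tr$sample_rate)
  expect_equal(extract_features(extract_concentric(tr_off)),
               extract_features(extract_concentric(tr)))
})

test_that("injected concentric duration is recovered within two samples", {
  a <- athlete_params("A06")
  for (D in c(0, 0.08, 0.2)) {
    tr <- simulate_trace(a, D, seed = 11)
    truth <- attr(tr, "truth")
    ft <- extract_features(extract_concentric(tr))
    expect_lte(abs(ft$t_con - truth$t_con), 2 / tr$sample_rate)
  }
})
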