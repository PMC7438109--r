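test_that("vergence and mean eye follow their sign conventions and invert", {
  # both eyes rotated nasally: right eye -5 (leftward), left eye +5
  expect_equal(compute_vergence(-5, 5), -10)   # converged
  expect_equal(compute_vergence(5, -5), 10)    # diverged
  expect_equal(compute_vergence(7, 7), 0)      # conjugate
  expect_equal(compute_mean_eye(10, 10), 10)
  expect_equal(compute_mean_eye(10, -10), 0)
  expect_error(compute_vergence(1:3, 1:2), "mismatched")
  expect_error(compute_mean_eye(1:3, 1:2), "mismatched")

  set.seed(51)
  r <- rnorm(100); l <- rnorm(100)
  E <- compute_mean_eye(r, l); V <- compute_vergence(r, l)
  expect_equal(E + V / 2, r)
  expect_equal(E - V / 2, l)
})

test_that("gaze is head plus eye on the unwrapped line", {
  expect_equal(compute_gaze(30, -30), 0)
  t <- (0:99) / 60
  yaw <- wrap_angle(100 * t + 150)  # crosses the seam
  G <- compute_gaze(yaw, rep(0, 100))
  expect_equal(diff(G), rep(100 / 60, 99), tolerance = 1e-9)
  # G - H = E wherever valid
  E <- rnorm(100)
  expect_equal(compute_gaze(yaw, E) - unwrap_angle(yaw), E)
})

test_that("central-difference velocity handles ramps, steps and ends", {
  rate <- 60
  ramp <- 3 * (0:59) / rate
  expect_equal(compute_velocity(ramp, rate), rep(3, 60))
  expect_equal(compute_velocity(rep(2, 10), rate), rep(0, 10))
  # a single-frame 6 deg step at 60 Hz peaks at 6*60/2 = 180 deg/s
  x <- c(rep(0, 30), rep(6, 30))
  v <- compute_velocity(x, rate)
  expect_equal(max(v), 180)
  expect_equal(sum(v > 0), 2)  # spread over the two neighbouring samples
  expect_error(compute_velocity(1:2, rate), "3 samples")
})

test_that("gaze samples partition into compensatory and saccadic at 180 deg/s", {
  gv <- c(200, 100, 180, -181, NA)
  lab <- classify_gaze_samples(gv)
  expect_equal(lab, c("saccadic", "compensatory", "compensatory", "saccadic", NA))
  # every valid sample gets exactly one label
  set.seed(52)
  gv2 <- rnorm(1000, 0, 200)
  lab2 <- classify_gaze_samples(gv2)
  expect_true(all(lab2 %in% c("compensatory", "saccadic")))
})

test_that("fixation segmentation keeps maximal compensatory runs above the minimum", {
  rate <- 60
  lab <- rep("compensatory", 120)
  fx <- segment_fixations(lab, rate)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 2000)

  lab2 <- c(rep("compensatory", 2), "saccadic", rep("compensatory", 60))
  fx2 <- segment_fixations(lab2, rate, min_duration_ms = 50)
  expect_equal(nrow(fx2), 1)  # the 2-sample (33 ms) run is dropped
  expect_equal(fx2$start_frame, 4)
})

test_that("saccade detection merges split runs and measures amplitude", {
  rate <- 60
  G <- c(rep(0, 10), rep(20, 10))
  gv <- compute_velocity(G, rate)
  lab <- classify_gaze_samples(gv)
  sac <- detect_saccades(lab, G, gv, rate)
  expect_equal(nrow(sac), 1)
  expect_equal(sac$amplitude, 20, tolerance = 1e-9)
  expect_equal(sac$onset_frame, 10L)
  expect_gt(sac$peak_velocity, 500)

  # two suprathreshold runs separated by one compensatory sample merge
  lab2 <- c(rep("compensatory", 5), "saccadic", "compensatory", "saccadic",
            rep("compensatory", 5))
  G2 <- seq_along(lab2) * 1.0
  gv2 <- rep(0, length(lab2))
  sac2 <- detect_saccades(lab2, G2, gv2, rate, merge_gap_samples = 1)
  expect_equal(nrow(sac2), 1)
  sac2b <- detect_saccades(lab2, G2, gv2, rate, merge_gap_samples = 0)
  expect_equal(nrow(sac2b), 2)

  none <- detect_saccades(rep("compensatory", 20), rep(0, 20), rep(0, 20), rate)
  expect_equal(nrow(none), 0)
})

test_that("RMS stabilization is zero for constant gaze and tracks injected noise", {
  rate <- 60
  lab <- rep("compensatory", 3000)
  fx <- segment_fixations(lab, rate)
  expect_equal(rms_stabilization(rep(4, 3000), fx)$median, 0)

  set.seed(53)
  lab_s <- lab
  lab_s[seq(150, 3000, by = 150)] <- "saccadic"  # ~20 fixations of 149 samples
  fx_s <- segment_fixations(lab_s, rate)
  sigma <- 2
  noisy <- rms_stabilization(rnorm(3000, 10, sigma), fx_s)
  expect_lt(abs(noisy$median - sigma) / sigma, 0.1)

  # a ramping head with constant gaze: head RMS exceeds gaze RMS
  head <- seq(0, 100, length.out = 3000)
  expect_gt(rms_stabilization(head, fx_s)$median,
            rms_stabilization(rep(0, 3000), fx_s)$median)
  expect_error(rms_stabilization(1:10, fx_s[0, ]), "empty")
})

test_that("a perfect-VOR session yields constant gaze, no saccades, one fixation", {
  s <- cached_session("vor60", sim_params(seed = 5, duration_s = 60,
                                          vor_gain = 1,
                                          saccade_trigger_deg = Inf,
                                          sigma_meas_deg = 0,
                                          vergence_noise_sd = 0,
                                          pitch_vergence_slope = 0))
  a <- analyze_gaze(s)
  expect_equal(nrow(s$truth$saccades), 0)
  expect_equal(nrow(a$saccades), 0)
  expect_equal(nrow(a$fixations), 1)
  expect_lt(rms_stabilization(a$gaze, a$fixations)$median, 1e-9)
  expect_gt(rms_stabilization(unwrap_angle(a$kin$yaw_meas),
                              a$fixations)$median, 1)
})

test_that("the gaze pipeline verb adds consistent derived columns", {
  s <- default_session()
  kin <- add_gaze_channels(s$kinematics, s$params$rate,
                           eye_r = "theta_r_meas", eye_l = "theta_l_meas",
                           yaw = "yaw_meas")
  expect_true(all(c("vergence", "mean_eye", "gaze", "gaze_velocity",
                    "gaze_label") %in% names(kin)))
  expect_equal(kin$gaze - unwrap_angle(kin$yaw_meas), kin$mean_eye)
  expect_true(all(kin$gaze_label[!is.na(kin$gaze_label)] %in%
                    c("compensatory", "saccadic")))
})
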