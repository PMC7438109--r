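test_that("ellipse fit recovers circles and general ellipses exactly", {
  circ <- ellipse_points(100, 100, 10, 10, 0)
  f <- fit_pupil_ellipse(circ)
  expect_equal(c(f$cx, f$cy), c(100, 100), tolerance = 1e-9)
  expect_equal(f$a, 10, tolerance = 1e-9)
  expect_equal(f$e, 1, tolerance = 1e-9)

  pts <- ellipse_points(50, 40, 10, 6, 30)
  f2 <- fit_pupil_ellipse(pts)
  expect_equal(c(f2$cx, f2$cy, f2$a, f2$b, f2$phi), c(50, 40, 10, 6, 30),
               tolerance = 1e-6)
})

test_that("ellipse fit rejects degenerate input", {
  line <- data.frame(x = 1:8, y = 2 * (1:8) + 1)
  expect_error(fit_pupil_ellipse(line), "collinear|degenerate|ellipse")
  few <- ellipse_points(0, 0, 5, 3, 10)[1:4, ]
  expect_error(fit_pupil_ellipse(few), "5 valid points")
  # low-confidence points are excluded before the count check
  pts <- ellipse_points(0, 0, 5, 3, 10)
  pts$likelihood <- c(rep(1, 4), rep(0.1, 4))
  expect_error(fit_pupil_ellipse(pts), "5 valid points")
})

test_that("ellipse fit is equivariant under rotation and translation", {
  set.seed(5)
  base <- ellipse_points(0, 0, 9, 5, 20, noise = 0.01)
  f0 <- fit_pupil_ellipse(base)
  rot <- apply_rigid(as.matrix(base), 40, 7, -3)
  f1 <- fit_pupil_ellipse(data.frame(x = rot[, 1], y = rot[, 2]))
  expect_equal(f1$a, f0$a, tolerance = 1e-8)
  expect_equal(f1$b, f0$b, tolerance = 1e-8)
  c1 <- apply_rigid(matrix(c(f0$cx, f0$cy), 1), 40, 7, -3)
  expect_equal(c(f1$cx, f1$cy), as.vector(c1), tolerance = 1e-8)
  expect_equal(mousegaze::wrap_angle(f1$phi - (f0$phi + 40)) %% 180, 0,
               tolerance = 1e-6)
})

test_that("camera-axis center follows from perpendicular major axes", {
  # two frames with orthogonal major axes: exact intersection
  ell <- tibble::tibble(cx = c(330, 320), cy = c(240, 250),
                        phi = c(90, 0), e = c(0.9, 0.9))
  cc <- estimate_camera_center(ell)
  expect_equal(as.numeric(cc), c(320, 240), tolerance = 1e-9,
               ignore_attr = TRUE)

  # nearly circular frames carry no constraint
  circ <- tibble::tibble(cx = 1:10, cy = 1, phi = runif(10, -90, 90),
                         e = 0.997)
  expect_error(estimate_camera_center(circ), "ellipticity")

  # parallel major axes leave the center unidentified along them
  par <- tibble::tibble(cx = c(300, 310, 315), cy = c(200, 200, 200),
                        phi = 0, e = 0.9)
  expect_error(estimate_camera_center(par), "parallel")
})

test_that("scale factor follows the ellipticity model |p-c| = R sqrt(1-e^2)", {
  ell <- tibble::tibble(cx = 320 + 30, cy = 240, phi = 90, e = cos(pi / 6))
  expect_equal(estimate_scale(ell, c(320, 240)), 30 / sin(pi / 6),
               tolerance = 1e-9)
  circ <- tibble::tibble(cx = 320, cy = 240, phi = 0, e = 1)
  expect_error(estimate_scale(circ, c(320, 240), min_eccentricity = 0),
               "circular")
})

test_that("calibration recovers the projection model exactly without noise", {
  set.seed(11)
  th <- runif(500, -30, 30)
  tv <- runif(500, -30, 30)
  truth <- list(cx = 320, cy = 240, R = 60)
  proj <- project_pupil(th, tv, truth)
  cal <- calibrate_eye(proj)
  expect_equal(c(cal$cx, cal$cy), c(320, 240), tolerance = 1e-6)
  expect_equal(cal$R, 60, tolerance = 1e-6)
  ang <- pupil_to_angle(proj, cal)
  expect_lt(max(abs(ang$theta_h - th)), 0.2)
  expect_lt(max(abs(ang$theta_v - tv)), 0.2)
  expect_error(calibrate_eye(proj[0, ]), "empty")
})

test_that("calibration degrades gracefully with edge-point noise", {
  set.seed(12)
  th <- runif(400, -30, 30)
  tv <- runif(400, -30, 30)
  truth <- list(cx = 320, cy = 240, R = 60)
  err_c <- sapply(c(0, 0.1, 0.5), function(sigma) {
    proj <- project_pupil(th, tv, truth, edge_points = TRUE, noise_px = sigma)
    ell <- fit_pupil_ellipses(attr(proj, "points"))
    cal <- calibrate_eye(ell)
    sqrt((cal$cx - 320)^2 + (cal$cy - 240)^2) +
      abs(cal$R - 60)
  })
  expect_lt(err_c[1], 1e-6)
  expect_true(all(diff(err_c) > -0.2))  # monotone up to estimator noise
  # at 0.5 px: center within 2 px and R within 3%
  proj <- project_pupil(th, tv, truth, edge_points = TRUE, noise_px = 0.5)
  cal <- calibrate_eye(fit_pupil_ellipses(attr(proj, "points")))
  expect_lt(sqrt((cal$cx - 320)^2 + (cal$cy - 240)^2), 2)
  expect_lt(abs(cal$R - 60) / 60, 0.03)
})

test_that("scale estimate is invariant to joint translation of pupils and center", {
  set.seed(13)
  th <- runif(100, -25, 25)
  tv <- runif(100, -25, 25)
  proj <- project_pupil(th, tv, list(cx = 320, cy = 240, R = 60))
  R0 <- estimate_scale(proj, c(320, 240))
  shifted <- dplyr::mutate(proj, cx = cx + 55, cy = cy - 31)
  expect_equal(estimate_scale(shifted, c(320 + 55, 240 - 31)), R0,
               tolerance = 1e-12)
})

test_that("pupil displacement converts to angle by the inverse projection", {
  cal <- structure(list(cx = 320, cy = 240, R = 60), class = "eye_calibration")
  on_axis <- pupil_to_angle(tibble::tibble(cx = 320, cy = 240), cal)
  expect_equal(c(on_axis$theta_h, on_axis$theta_v), c(0, 0))
  half <- pupil_to_angle(tibble::tibble(cx = 350, cy = 240), cal)
  expect_equal(half$theta_h, 30, tolerance = 1e-9)
  expect_equal(half$theta_v, 0)
  # outside the model: clipped and flagged
  expect_warning(out <- pupil_to_angle(tibble::tibble(cx = 400, cy = 240), cal),
                 "clipped")
  expect_equal(out$theta_h, 90)
  expect_true(out$clipped)
  # per-eye sign map flips the head-frame convention
  flip <- pupil_to_angle(tibble::tibble(cx = 350, cy = 240), cal, sign_h = -1)
  expect_equal(flip$theta_h, -30, tolerance = 1e-9)
})

test_that("centering re-references eye angles to the valid-sample mean", {
  eyes <- tibble::tibble(theta_h = rep(7, 10), theta_v = rep(-2, 10))
  out <- center_eye_positions(eyes)
  expect_equal(out$theta_h, rep(0, 10))
  expect_equal(out$theta_v, rep(0, 10))

  set.seed(3)
  eyes2 <- tibble::tibble(theta_h = rnorm(50), theta_v = rnorm(50),
                          valid = rep(c(TRUE, FALSE), 25))
  out2 <- center_eye_positions(eyes2)
  expect_equal(mean(out2$theta_h[eyes2$valid]), 0)
  expect_equal(mean(out2$theta_v[eyes2$valid]), 0)
  expect_error(center_eye_positions(tibble::tibble(theta_h = NA_real_,
                                                   theta_v = NA_real_)),
               "no valid samples")
})

test_that("stationary-period error estimator matches the injected noise level", {
  n <- 20000
  still <- rep(0.5, n)
  rot <- rep(0, n)
  expect_equal(estimate_eye_measurement_error(rep(3, n), still, rot), 0)

  set.seed(21)
  sigma <- 0.5
  noisy <- rnorm(n, 0, sigma)
  est <- estimate_eye_measurement_error(noisy, still, rot)
  expect_lt(abs(est - sigma) / sigma, 0.05)
  est_w <- estimate_eye_measurement_error(noisy, still, rot, method = "window")
  expect_lt(abs(est_w - sigma) / sigma, 0.05)

  expect_error(estimate_eye_measurement_error(noisy, rep(10, n), rot),
               "no stationary")
})
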