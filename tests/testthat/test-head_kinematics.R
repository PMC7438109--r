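make_landmark_frames <- function(shape, yaws, txs, tys, noise = 0,
                                 pts = sprintf("p%d", seq_len(nrow(shape)))) {
  frames <- lapply(seq_along(yaws), function(i) {
    q <- apply_rigid(shape, yaws[i], txs[i], tys[i])
    if (noise > 0) q <- q + matrix(rnorm(length(q), 0, noise), ncol = 2)
    tibble::tibble(frame = i - 1L, point = pts, x = q[, 1], y = q[, 2],
                   likelihood = 1)
  })
  dplyr::bind_rows(frames)
}

test_that("mean geometry recovers a rigid shape family up to congruence", {
  set.seed(31)
  shape <- test_head_shape()
  lm <- make_landmark_frames(shape, runif(30, -180, 180),
                             runif(30, -5, 5), runif(30, -5, 5))
  tpl <- compute_mean_geometry(lm, nose = "p1", head_center = "p2")
  # congruent: every pairwise distance preserved
  d_tpl <- dist(cbind(tpl$x, tpl$y))
  d_true <- dist(shape[order(sprintf("p%d", 1:8)), ])
  expect_equal(as.vector(d_tpl), as.vector(d_true), tolerance = 1e-6)
  # oriented: head_center -> nose along +x
  i_nose <- match("p1", tpl$point); i_ctr <- match("p2", tpl$point)
  v <- c(tpl$x[i_nose] - tpl$x[i_ctr], tpl$y[i_nose] - tpl$y[i_ctr])
  expect_equal(atan2(v[2], v[1]), 0, tolerance = 1e-6)
})

test_that("mean geometry averages away landmark noise", {
  set.seed(32)
  shape <- test_head_shape()
  sigma <- 0.2
  n_frames <- 200
  lm <- make_landmark_frames(shape, runif(n_frames, -180, 180),
                             runif(n_frames, -5, 5), runif(n_frames, -5, 5),
                             noise = sigma)
  tpl <- compute_mean_geometry(lm, nose = "p1", head_center = "p2")
  d_tpl <- as.vector(dist(cbind(tpl$x, tpl$y)))
  d_true <- as.vector(dist(shape[order(sprintf("p%d", 1:8)), ]))
  # coordinate error ~ sigma/sqrt(n_frames); allow a generous multiple
  expect_lt(max(abs(d_tpl - d_true)), 5 * sigma / sqrt(n_frames) * 3)

  lm2 <- lm
  lm2$likelihood <- 0.1
  expect_error(compute_mean_geometry(lm2), "at least 10 frames")
})

test_that("rigid pose fit inverts a known rotation and translation", {
  shape <- test_head_shape()
  tpl <- tibble::tibble(point = sprintf("p%d", 1:8),
                        x = shape[, 1] - mean(shape[, 1]),
                        y = shape[, 2] - mean(shape[, 2]))
  q <- apply_rigid(as.matrix(tpl[, c("x", "y")]), 90, 5, 5)
  fit <- fit_rigid_pose(data.frame(point = tpl$point, x = q[, 1], y = q[, 2]),
                        tpl)
  expect_equal(fit$yaw, 90, tolerance = 1e-9)
  expect_equal(c(fit$x, fit$y), c(5, 5), tolerance = 1e-9)
  expect_lt(fit$residual, 1e-9)

  one <- data.frame(point = "p1", x = 1, y = 1, likelihood = 1)
  expect_false(fit_rigid_pose(one, tpl)$valid)
})

test_that("closed-form rigid fit agrees with a dense rotation-grid search", {
  set.seed(33)
  shape <- test_head_shape()
  tpl_xy <- sweep(shape, 2, colMeans(shape))
  tpl <- tibble::tibble(point = sprintf("p%d", 1:8),
                        x = tpl_xy[, 1], y = tpl_xy[, 2])
  for (i in 1:25) {
    yaw <- runif(1, -180, 180)
    q <- apply_rigid(tpl_xy, yaw, runif(1, -10, 10), runif(1, -10, 10)) +
      matrix(rnorm(16, 0, 0.3), ncol = 2)
    fit <- fit_rigid_pose(data.frame(point = tpl$point, x = q[, 1], y = q[, 2]),
                          tpl)
    oracle <- brute_force_yaw(tpl_xy, q)
    expect_lt(abs(wrap_angle(fit$yaw - oracle)), 0.011)
  }
})

test_that("rigid fit is equivariant under a global frame transform", {
  set.seed(34)
  shape <- test_head_shape()
  tpl_xy <- sweep(shape, 2, colMeans(shape))
  tpl <- tibble::tibble(point = sprintf("p%d", 1:8),
                        x = tpl_xy[, 1], y = tpl_xy[, 2])
  q <- apply_rigid(tpl_xy, 25, 3, -4) + matrix(rnorm(16, 0, 0.2), ncol = 2)
  f0 <- fit_rigid_pose(data.frame(point = tpl$point, x = q[, 1], y = q[, 2]), tpl)
  # rotate the whole arena by 60 deg and shift
  q2 <- apply_rigid(q, 60, 11, -7)
  f1 <- fit_rigid_pose(data.frame(point = tpl$point, x = q2[, 1], y = q2[, 2]), tpl)
  expect_equal(wrap_angle(f1$yaw - f0$yaw), 60, tolerance = 1e-9)
  c1 <- apply_rigid(matrix(c(f0$x, f0$y), 1), 60, 11, -7)
  expect_equal(c(f1$x, f1$y), as.vector(c1), tolerance = 1e-9)
  expect_equal(f1$residual, f0$residual, tolerance = 1e-9)
})

test_that("speed is displacement times rate with median smoothing", {
  n <- 120
  expect_equal(compute_speed(rep(2, n), rep(3, n), 60), rep(0, n))
  x <- seq(0, by = 1, length.out = n)  # 1 cm per frame
  spd <- compute_speed(x, rep(0, n), 60)
  expect_equal(spd, rep(60, n))
  # a single-frame tracking glitch is suppressed by the 500 ms median
  xg <- x; xg[60] <- xg[60] + 30
  spd_g <- compute_speed(xg, rep(0, n), 60)
  disp <- c(NA, sqrt(diff(xg)^2) * 60)
  expect_equal(spd_g, naive_sliding_median(disp, 31))
  expect_lt(max(spd_g[50:70]), 100)
})

test_that("target geometry reports distance, signed azimuth and closing rate", {
  n <- 61
  head <- tibble::tibble(x = rep(0, n), y = rep(0, n), yaw = rep(0, n))
  tg <- target_geometry(head, rep(10, n), rep(0, n), 60)
  expect_equal(tg$distance, rep(10, n))
  expect_equal(tg$azimuth, rep(0, n))
  # cricket 90 deg to the right (negative y when heading +x)
  tg_r <- target_geometry(head, rep(0, n), rep(-5, n), 60)
  expect_equal(tg_r$azimuth, rep(90, n))
  expect_equal(tg_r$distance, rep(5, n))
  # closing at a constant 12 cm/s
  t <- (seq_len(n) - 1) / 60
  head2 <- tibble::tibble(x = 12 * t, y = rep(0, n), yaw = rep(0, n))
  tg_c <- target_geometry(head2, rep(20, n), rep(0, n), 60)
  expect_equal(tg_c$range_rate[5:(n - 5)], rep(-12, n - 9), tolerance = 1e-9)
})

test_that("azimuth is zero exactly when the cricket lies on the head axis", {
  set.seed(35)
  for (i in 1:50) {
    yaw <- runif(1, -180, 180)
    d <- runif(1, 1, 30)
    hx <- runif(1, -10, 10); hy <- runif(1, -10, 10)
    on_axis <- c(hx + d * cos(yaw * pi / 180), hy + d * sin(yaw * pi / 180))
    head <- tibble::tibble(x = rep(hx, 3), y = rep(hy, 3), yaw = rep(yaw, 3))
    tg <- target_geometry(head, rep(on_axis[1], 3), rep(on_axis[2], 3), 60)
    expect_equal(tg$azimuth, rep(0, 3), tolerance = 1e-9)
  }
})

test_that("IMU processing extracts tilt from gravity and converts gyro units", {
  n <- 100
  imu <- tibble::tibble(t = (seq_len(n) - 1) / 50,
                        ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0.5)
  out <- process_imu(imu)
  expect_equal(out$pitch, rep(0, n))
  expect_equal(out$roll, rep(0, n))
  expect_equal(out$yaw_rate, rep(0.5 * 180 / pi, n))

  imu2 <- dplyr::mutate(imu, ax = 9.81, az = 0)
  expect_equal(process_imu(imu2)$pitch, rep(90, n))

  imu3 <- dplyr::mutate(imu, ax = 12)  # beyond gravity: clipped + flagged
  out3 <- process_imu(imu3)
  expect_equal(out3$pitch, rep(90, n))
  expect_true(all(out3$clipped))
})

test_that("head measurement error compares IMU and landmark yaw per frame", {
  n <- 5000
  yaw <- cumsum(rnorm(n, 0, 1))
  rate <- 60
  yaw_rate <- c(0, diff(yaw)) * rate
  expect_equal(estimate_head_measurement_error(yaw, yaw_rate, rate), 0)

  set.seed(36)
  sigma <- 0.5
  noisy <- yaw + rnorm(n, 0, sigma)
  est <- estimate_head_measurement_error(noisy, yaw_rate, rate)
  expect_lt(abs(est - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.05)

  expect_error(estimate_head_measurement_error(rep(NA_real_, 5), rep(0, 5), 60),
               "no overlapping")
})
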