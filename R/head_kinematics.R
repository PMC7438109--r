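#' Estimate the mean head geometry by generalized Procrustes alignment
#'
#' Builds the rigid template ("defined mean geometry") that every frame's
#' head landmarks are later fit against. Frames are iteratively aligned to
#' the running mean by rotation + translation only (no scaling: the
#' landmark set is a rigid implant/head constellation) until the template
#' stabilizes. The template is centered on its centroid and, when the two
#' reference points are present, rotated so the line from the head center
#' to the nose lies along +x; fitted yaw then directly equals head
#' direction.
#'
#' @param landmarks Long landmark tibble (columns `frame`, `point`, `x`,
#'   `y`, `likelihood`).
#' @param nose,head_center Names of the two points that define head
#'   direction.
#' @param conf_threshold Minimum point confidence.
#' @param n_iter Maximum Procrustes iterations.
#' @param tol Convergence tolerance on the template coordinates.
#' @return Object of class `head_template`: tibble with `point`, `x`, `y`
#'   (template coordinates, centroid at origin).
#' @export
compute_mean_geometry <- function(landmarks, nose = "nose",
                                  head_center = "head_center",
                                  conf_threshold = 0.9,
                                  n_iter = 50, tol = 1e-6) {
  wide <- landmarks |>
    dplyr::mutate(ok = !is.na(.data$x) & !is.na(.data$y) &
                    .data$likelihood >= conf_threshold)
  pts <- sort(unique(wide$point))
  frames <- split(wide, wide$frame)
  frames <- Filter(function(d) sum(d$ok) >= 3, frames)
  if (length(frames) < 10) {
    stop("mean geometry needs at least 10 frames with >= 3 valid points",
         call. = FALSE)
  }
  # initial template: first frame with all points valid, else first usable
  init <- Filter(function(d) all(d$ok), frames)
  d0 <- if (length(init)) init[[1]] else frames[[1]]
  d0 <- d0[match(pts, d0$point), ]
  tpl <- cbind(d0$x, d0$y)
  tpl[!d0$ok, ] <- NA
  tpl <- sweep(tpl, 2, colMeans(tpl, na.rm = TRUE))
  for (iter in seq_len(n_iter)) {
    acc <- matrix(0, length(pts), 2)
    wsum <- numeric(length(pts))
    for (d in frames) {
      d <- d[match(pts, d$point), ]
      fit <- rigid_fit_core(tpl, cbind(d$x, d$y),
                            w = ifelse(d$ok, d$likelihood, 0))
      if (is.null(fit)) next
      # map the frame back into template space
      Rm <- rot2(-fit$theta)
      back <- sweep(cbind(d$x, d$y), 2, fit$t) %*% t(Rm)
      w <- ifelse(d$ok & !is.na(back[, 1]), d$likelihood, 0)
      acc <- acc + back * w
      wsum <- wsum + w
    }
    if (all(wsum == 0)) stop("degenerate landmark data", call. = FALSE)
    new_tpl <- acc / wsum
    new_tpl <- sweep(new_tpl, 2, colMeans(new_tpl, na.rm = TRUE))
    delta <- max(abs(new_tpl - tpl), na.rm = TRUE)
    tpl <- new_tpl
    if (is.finite(delta) && delta < tol) break
  }
  if (qr(stats::na.omit(tpl))$rank < 2) {
    stop("degenerate mean geometry: landmarks are collinear", call. = FALSE)
  }
  # orient template so head_center -> nose points along +x
  if (all(c(nose, head_center) %in% pts)) {
    v <- tpl[match(nose, pts), ] - tpl[match(head_center, pts), ]
    ang <- atan2(v[2], v[1])
    tpl <- tpl %*% t(rot2(-ang))
  }
  structure(tibble::tibble(point = pts, x = tpl[, 1], y = tpl[, 2]),
            class = c("head_template", class(tibble::tibble())))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# weighted closed-form 2-D rigid fit: finds rotation theta and translation t
# minimizing sum w_i |q_i - R p_i - t|^2; returns NULL when underdetermined
rigid_fit_core <- function(p, q, w) {
  ok <- !is.na(p[, 1]) & !is.na(q[, 1]) & !is.na(w) & w > 0
  if (sum(ok) < 2) return(NULL)
  p <- p[ok, , drop = FALSE]
  q <- q[ok, , drop = FALSE]
  w <- w[ok]
  wp <- colSums(p * w) / sum(w)
  wq <- colSums(q * w) / sum(w)
  pc <- sweep(p, 2, wp)
  qc <- sweep(q, 2, wq)
  num <- sum(w * (pc[, 1] * qc[, 2] - pc[, 2] * qc[, 1]))
  den <- sum(w * (pc[, 1] * qc[, 1] + pc[, 2] * qc[, 2]))
  if (num == 0 && den == 0) return(NULL)
  theta <- atan2(num, den)
  Rm <- rot2(theta)
  t <- wq - as.vector(Rm %*% wp)
  resid <- sqrt(sum(w * rowSums((qc - pc %*% t(Rm))^2)) / sum(w))
  list(theta = theta, t = t, residual = resid, n = sum(ok))
}

#' Fit a rigid pose (translation + rotation) for one landmark frame
#'
#' Closed-form weighted 2-D rigid least squares of the frame's points
#' against the head template. Yaw is reported in degrees, counter-clockwise
#' positive viewed from above, wrapped to (-180, 180]; with a template
#' oriented by [compute_mean_geometry()] it equals the head direction (the
#' nose to head-center line).
#'
#' @param frame_points Data frame with `point`, `x`, `y` and optionally
#'   `likelihood` for one frame.
#' @param template A `head_template`.
#' @param conf_threshold Points below this confidence get weight 0.
#' @param origin Template-frame coordinates `c(x, y)` reported as the pose
#'   position after transformation; default the template centroid. Pass the
#'   template's head-center point to report head-center position.
#' @return List with `x`, `y` (the transformed `origin`), `yaw` (degrees),
#'   `residual` (same units as input), `n`, `valid`. Underdetermined
#'   frames (< 2 usable points) return `valid = FALSE` with NA pose.
#' @export
fit_rigid_pose <- function(frame_points, template, conf_threshold = 0.9,
                           origin = c(0, 0)) {
  d <- as.data.frame(frame_points)
  idx <- match(template$point, d$point)
  q <- cbind(d$x[idx], d$y[idx])
  w <- if (is.null(d$likelihood)) rep(1, length(idx)) else d$likelihood[idx]
  w[is.na(w)] <- 0
  w[w < conf_threshold] <- 0
  fit <- rigid_fit_core(cbind(template$x, template$y), q, w)
  if (is.null(fit)) {
    return(list(x = NA_real_, y = NA_real_, yaw = NA_real_,
                residual = NA_real_, n = 0L, valid = FALSE))
  }
  pos <- as.vector(rot2(fit$theta) %*% origin) + fit$t
  list(x = pos[1], y = pos[2], yaw = wrap_angle(rad2deg(fit$theta)),
       residual = fit$residual, n = fit$n, valid = TRUE)
}

#' Fit head pose for every frame of a landmark table
#'
#' @param landmarks Long landmark tibble of the overhead camera's head
#'   points.
#' @param origin_point Template point reported as the pose position
#'   (default the head center, matching the distance/azimuth reference);
#'   NULL reports the template centroid.
#' @inheritParams fit_rigid_pose
#' @return Tibble with `frame`, `t` (when present), `x`, `y`, `yaw`
#'   (degrees, wrapped), `residual`, `valid`.
#' @export
fit_head_poses <- function(landmarks, template, conf_threshold = 0.9,
                           origin_point = "head_center") {
  origin <- c(0, 0)
  if (!is.null(origin_point) && origin_point %in% template$point) {
    i <- match(origin_point, template$point)
    origin <- c(template$x[i], template$y[i])
  }
  landmarks |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_rigid_pose(d, template, conf_threshold, origin = origin)
      tibble::tibble(t = if ("t" %in% names(d)) d$t[1] else NA_real_,
                     x = fit$x, y = fit$y, yaw = fit$yaw,
                     residual = fit$residual, valid = fit$valid)
    }) |>
    dplyr::ungroup()
}

#' Head movement speed with the standard smoothing
#'
#' Frame-to-frame Euclidean displacement times the sampling rate, median
#' filtered over 500 ms. The first sample has no preceding frame and is NA
#' before filtering (the shrinking median window fills it from its
#' neighbours).
#'
#' @param x,y Head-center position series (cm).
#' @param rate Sampling rate, Hz.
#' @param window_ms Median-filter window (ms).
#' @return Speed series in cm/s, same length as `x`.
#' @export
compute_speed <- function(x, y, rate, window_ms = 500) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  disp <- sqrt(diff(x)^2 + diff(y)^2) * rate
  median_filter(c(NA_real_, disp), window_ms, rate)
}

#' Distance, azimuth and closing rate to the target
#'
#' Computes per-sample cricket-relative geometry: distance from the head
#' center, azimuth of the cricket relative to head direction (0 = head
#' pointing at the cricket; by default positive = cricket to the right of
#' the head axis), and range rate (the smoothed time derivative of
#' distance; negative while closing).
#'
#' @param head Tibble with head pose columns `x`, `y` (cm), `yaw`
#'   (degrees).
#' @param cricket_x,cricket_y Cricket position series (cm), synchronized
#'   with `head`.
#' @param rate Sampling rate, Hz.
#' @param window_ms Median-filter window for the range rate (ms); the same
#'   smoothing as speed.
#' @param azimuth_sign +1 (default): cricket right of the head axis gives
#'   positive azimuth; -1 flips the convention.
#' @return Tibble with `distance` (cm), `azimuth` (degrees, (-180, 180]),
#'   `range_rate` (cm/s).
#' @export
target_geometry <- function(head, cricket_x, cricket_y, rate,
                            window_ms = 500, azimuth_sign = 1) {
  n <- nrow(head)
  stopifnot(length(cricket_x) == n, length(cricket_y) == n)
  dx <- cricket_x - head$x
  dy <- cricket_y - head$y
  distance <- sqrt(dx^2 + dy^2)
  bearing <- rad2deg(atan2(dy, dx))
  azimuth <- azimuth_sign * wrap_angle(head$yaw - bearing)
  # central-difference range rate, one-sided at the ends, then smoothed
  dr <- rep(NA_real_, n)
  if (n >= 3) dr[2:(n - 1)] <- (distance[3:n] - distance[1:(n - 2)]) * rate / 2
  if (n >= 2) {
    dr[1] <- (distance[2] - distance[1]) * rate
    dr[n] <- (distance[n] - distance[n - 1]) * rate
  }
  range_rate <- median_filter(dr, window_ms, rate)
  tibble::tibble(distance = distance, azimuth = azimuth, range_rate = range_rate)
}

#' Derive head pitch, roll and yaw rate from inertial channels
#'
#' Accelerometer channels are median filtered (266.7 ms by default) to
#' remove rapid transients, then head tilt is extracted from the gravity
#' component: `pitch = asin(a_forward / g)` (positive nose-up) and
#' `roll = asin(a_lateral / g)`. Gyroscope channels are used unfiltered;
#' the yaw-axis channel is converted to degrees per second. Samples whose
#' filtered acceleration exceeds gravity are clipped to +/-90 degrees and
#' flagged.
#'
#' @param imu Tibble from [read_imu_csv()] (columns `t`, `ax`..`gz` in
#'   m/s^2 and rad/s).
#' @param axis_map Which sensor axes are forward, lateral and yaw; a named
#'   list of column names.
#' @param g Gravitational acceleration, m/s^2.
#' @param window_ms Accelerometer median-filter window (ms).
#' @param rate Sampling rate (Hz); estimated from `t` when NULL.
#' @return Tibble with `t`, `pitch`, `roll` (degrees), `yaw_rate` (deg/s),
#'   `clipped`.
#' @export
process_imu <- function(imu,
                        axis_map = list(forward = "ax", lateral = "ay",
                                        yaw = "gz"),
                        g = 9.81, window_ms = 266.7, rate = NULL) {
  if (is.null(rate)) rate <- 1 / stats::median(diff(imu$t))
  af <- median_filter(imu[[axis_map$forward]], window_ms, rate)
  al <- median_filter(imu[[axis_map$lateral]], window_ms, rate)
  uf <- af / g
  ul <- al / g
  clipped <- (!is.na(uf) & abs(uf) > 1) | (!is.na(ul) & abs(ul) > 1)
  tibble::tibble(
    t = imu$t,
    pitch = rad2deg(asin(clamp(uf, -1, 1))),
    roll = rad2deg(asin(clamp(ul, -1, 1))),
    yaw_rate = rad2deg(imu[[axis_map$yaw]]),
    clipped = clipped
  )
}

#' Estimate head-angle measurement error from IMU vs landmark yaw
#'
#' Compares the two independent per-frame estimates of head yaw rotation:
#' the frame-to-frame change of landmark-fitted yaw and the integrated
#' gyroscope yaw rate. Returns the RMS difference per frame in degrees,
#' an upper bound on the combined error of the two measurements.
#'
#' @param yaw_landmark Landmark-derived yaw series (degrees, wrapped ok).
#' @param yaw_rate_imu Gyroscope yaw rate (deg/s), same timebase.
#' @param rate Sampling rate (Hz).
#' @return RMS difference in degrees per frame.
#' @export
estimate_head_measurement_error <- function(yaw_landmark, yaw_rate_imu, rate) {
  n <- length(yaw_landmark)
  stopifnot(length(yaw_rate_imu) == n, n >= 2)
  d_lmk <- wrap_angle(diff(yaw_landmark))
  d_imu <- (yaw_rate_imu / rate)[-1]
  ok <- !is.na(d_lmk) & !is.na(d_imu)
  if (!any(ok)) stop("no overlapping valid samples", call. = FALSE)
  sqrt(mean((d_lmk[ok] - d_imu[ok])^2))
}

#' Export a kinematic table to CSV
#'
#' @param kin Kinematic tibble (any combination of the pipeline's columns).
#' @param path Output path.
#' @export
write_kinematics_csv <- function(kin, path) {
  readr::write_csv(kin, path)
  invisible(path)
}
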