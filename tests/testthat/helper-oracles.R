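# Independent oracles and fixture builders shared across the suite.

# naive sliding median with clipped windows; the reference for median_filter
naive_sliding_median <- function(x, k) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

# points sampled on an ellipse given geometric parameters (degrees)
ellipse_points <- function(cx, cy, a, b, phi_deg, n = 8, noise = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  phi <- phi_deg * pi / 180
  x <- cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
  y <- cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  if (noise > 0) {
    x <- x + stats::rnorm(n, 0, noise)
    y <- y + stats::rnorm(n, 0, noise)
  }
  data.frame(x = x, y = y)
}

# direct shifted-Pearson cross-correlation; the reference for lagged_xcorr
shifted_pearson <- function(a, b, max_lag_samples) {
  lags <- seq(-max_lag_samples, max_lag_samples)
  n <- length(a)
  r <- vapply(lags, function(k) {
    i0 <- max(1, 1 - k)
    i1 <- min(n, n - k)
    if (i1 - i0 + 1 < 2) return(NA_real_)
    stats::cor(a[i0:i1], b[(i0 + k):(i1 + k)])
  }, numeric(1))
  data.frame(lag_samples = lags, r = r)
}

# dense rotation-grid search for the weighted 2-D rigid fit; reference for
# fit_rigid_pose. Returns the grid angle (degrees) minimizing the residual.
brute_force_yaw <- function(template_xy, frame_xy, w = NULL, step_deg = 0.01) {
  if (is.null(w)) w <- rep(1, nrow(template_xy))
  p <- sweep(template_xy, 2, colSums(template_xy * w) / sum(w))
  q <- sweep(frame_xy, 2, colSums(frame_xy * w) / sum(w))
  ang <- seq(-180, 180 - step_deg, by = step_deg) * pi / 180
  # residual(theta) = const - 2*(C cos + S sin); minimize by maximizing
  C <- sum(w * (p[, 1] * q[, 1] + p[, 2] * q[, 2]))
  S <- sum(w * (p[, 1] * q[, 2] - p[, 2] * q[, 1]))
  obj <- C * cos(ang) + S * sin(ang)
  ang[which.max(obj)] * 180 / pi
}

# random rigid transform of a point set
apply_rigid <- function(xy, theta_deg, tx, ty) {
  th <- theta_deg * pi / 180
  cbind(xy[, 1] * cos(th) - xy[, 2] * sin(th) + tx,
        xy[, 1] * sin(th) + xy[, 2] * cos(th) + ty)
}

# 8-point head constellation used in pose tests
test_head_shape <- function() {
  cbind(c(2.5, 0, -0.5, -0.5, 1.2, 1.2, -1.2, -1.2),
        c(0, 0, 1.1, -1.1, 0.8, -0.8, 0.6, -0.6))
}

# memoized synthetic sessions so several test files can share one build
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(key, params) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_session(params)
  }
  .session_cache[[key]]
}

default_session <- function() {
  cached_session("default42", sim_params(seed = 42))
}

long_session <- function() {
  cached_session("long42", sim_params(seed = 42, duration_s = 1200))
}

# run the measured channels of a session through the gaze pipeline
analyze_gaze <- function(session, threshold = 180) {
  kin <- session$kinematics
  rate <- session$params$rate
  E <- compute_mean_eye(kin$theta_r_meas, kin$theta_l_meas)
  G <- compute_gaze(kin$yaw_meas, E)
  gv <- compute_velocity(G, rate)
  lab <- classify_gaze_samples(gv, threshold)
  list(kin = kin, rate = rate, mean_eye = E, gaze = G, gaze_velocity = gv,
       labels = lab,
       saccades = detect_saccades(lab, G, gv, rate),
       fixations = segment_fixations(lab, rate))
}
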