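#' Simulation parameters for a synthetic prey-capture session
#'
#' Bundles the generator's settings with defaults chosen to emulate the
#' statistical structure the analysis assumes: pursuit bouts satisfying the
#' approach criteria inside a 45 x 38 cm arena, head yaw composed of a slow
#' body heading plus a fast scanning oscillation, vestibulo-ocular eye
#' movements with recentering saccades, pitch-coupled vergence, and about
#' half a degree of angular measurement noise.
#'
#' @param duration_s Session length, seconds.
#' @param rate Sampling rate, Hz.
#' @param arena_cm Arena width and height, cm.
#' @param vor_gain Vestibulo-ocular gain g: the eye counter-rotates by
#'   `-g * d(yaw)` between saccades. 1 = perfect stabilization.
#' @param saccade_trigger_deg Eye eccentricity (degrees) that triggers a
#'   recentering saccade; `Inf` disables saccades.
#' @param saccade_duration_frames Frames over which the eye resets to 0.
#' @param pitch_vergence_slope Coupling k in `V = k * P` (vergence degrees
#'   per degree of nose-up pitch; negative: nose-down pitch diverges the
#'   eyes).
#' @param pitch_tau_s,pitch_sd_explore,pitch_sd_approach Mean-reverting
#'   head-pitch process: time constant and stationary SD (degrees) outside
#'   and during approaches (pitch is stabilized while approaching).
#' @param yaw_osc_sd,yaw_osc_tau_s Fast head-scanning yaw oscillation
#'   around the body heading: stationary SD (degrees) and time constant.
#' @param explore_speed_mean,explore_speed_sd Locomotion speed process
#'   (cm/s) while exploring.
#' @param approach_speed_mean,approach_speed_sd Speed process while
#'   approaching (must comfortably exceed the 10 cm/s closing criterion).
#' @param speed_tau_s Speed process time constant, seconds.
#' @param explore_turn_sd Slow-heading turn-rate SD while exploring, deg/s.
#' @param turn_tau_s Turn-rate time constant, seconds.
#' @param approach_turn_gain Proportional steering gain toward the cricket
#'   during approach, 1/s.
#' @param approach_turn_max Steering saturation, deg/s.
#' @param explore_duration_mean_s Mean exploration-bout length before the
#'   next approach starts (exponential).
#' @param capture_radius_cm Distance at which the cricket is "caught" and
#'   relocates.
#' @param cricket_relocation_hz Poisson rate of spontaneous cricket
#'   relocation while the mouse explores.
#' @param vergence_noise_sd Vergence variability (degrees) beyond the pitch
#'   coupling.
#' @param eye_v_sd,eye_v_tau_s Vertical eye-position process (degrees,
#'   seconds).
#' @param sigma_meas_deg Gaussian measurement noise added to exported angle
#'   channels (eye angles, yaw, pitch), degrees.
#' @param sigma_pos_cm Measurement noise on exported positions, cm.
#' @param seed Integer master seed; sub-seeds are split from it per
#'   subsystem (behavior, eyes, measurement noise, export).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(duration_s = 600,
                       rate = 60,
                       arena_cm = c(45, 38),
                       vor_gain = 1,
                       saccade_trigger_deg = 32,
                       saccade_duration_frames = 4,
                       pitch_vergence_slope = -0.5,
                       pitch_tau_s = 0.7,
                       pitch_sd_explore = 10,
                       pitch_sd_approach = 3,
                       yaw_osc_sd = 14,
                       yaw_osc_tau_s = 0.08,
                       explore_speed_mean = 6,
                       explore_speed_sd = 3,
                       approach_speed_mean = 22,
                       approach_speed_sd = 3,
                       speed_tau_s = 1,
                       explore_turn_sd = 6,
                       turn_tau_s = 0.7,
                       approach_turn_gain = 8,
                       approach_turn_max = 250,
                       explore_duration_mean_s = 8,
                       capture_radius_cm = 2,
                       cricket_relocation_hz = 0.02,
                       vergence_noise_sd = 1,
                       eye_v_sd = 3,
                       eye_v_tau_s = 0.5,
                       sigma_meas_deg = 0.5,
                       sigma_pos_cm = 0,
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(p$rate > 0, p$duration_s > 0, p$vor_gain >= 0,
            p$saccade_duration_frames >= 1, p$sigma_meas_deg >= 0,
            p$sigma_pos_cm >= 0, all(p$arena_cm > 0))
  structure(p, class = "sim_params")
}

# one OU (mean-reverting) step: x' = mu + a (x - mu) + s sqrt(1-a^2) eps
ou_step <- function(x, mu, a, sd_stat, eps) {
  mu + a * (x - mu) + sd_stat * sqrt(1 - a^2) * eps
}

#' Simulate a synthetic prey-capture session with ground truth
#'
#' Generates mouse and cricket trajectories (smooth-turning exploration
#' alternating with proportional-steering pursuit until the cricket is
#' reached and relocates), head pitch (mean-reverting, stabilized during
#' approach), head yaw (slow heading plus fast scanning oscillation), and
#' per-eye horizontal angles driven by a vestibulo-ocular reflex with
#' recentering saccades: the mean eye integrates `-gain * d(yaw)` between
#' saccades and linearly resets to zero over a few frames whenever its
#' eccentricity exceeds the trigger. Vergence follows head pitch. Gaussian
#' measurement noise is added to the exported angle channels only; the
#' noiseless truth and a full event log are kept alongside.
#'
#' Everything is deterministic given `params$seed`.
#'
#' @param params A [sim_params()] list.
#' @return Object of class `synthetic_session`: list with
#'   \describe{
#'     \item{kinematics}{60 Hz tibble: `frame`, `t`, truth channels (`x`,
#'       `y`, `speed`, `yaw`, `yaw_unwrapped`, `pitch`, `cricket_x`,
#'       `cricket_y`, `distance`, `azimuth`, `range_rate`, `theta_r`,
#'       `theta_l`, `theta_v`, `gaze`, `approach`) and measured channels
#'       (`theta_r_meas`, `theta_l_meas`, `yaw_meas`, `pitch_meas`).}
#'     \item{truth}{list: `saccades` (tibble of onset/offset frames,
#'       amplitude), `fixations` (tibble of frame intervals), `approaches`
#'       (an `epoch_set`).}
#'     \item{params}{the `sim_params` used.}
#'   }
#' @export
simulate_session <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- as.integer(round(p$duration_s * p$rate))
  dt <- 1 / p$rate
  set.seed(p$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  ## ---- behavior: trajectory, heading, pitch -------------------------------
  set.seed(sub_seeds[1])
  a_turn <- exp(-dt / p$turn_tau_s)
  a_speed <- exp(-dt / p$speed_tau_s)
  a_pitch <- exp(-dt / p$pitch_tau_s)
  a_osc <- exp(-dt / p$yaw_osc_tau_s)
  eps_turn <- stats::rnorm(n)
  eps_speed <- stats::rnorm(n)
  eps_pitch <- stats::rnorm(n)
  eps_osc <- stats::rnorm(n)
  u_capture <- stats::runif(n)   # cricket relocation draws
  u_bout <- stats::rexp(50000, 1 / p$explore_duration_mean_s)

  x <- y <- heading <- pitch <- speed <- osc <- numeric(n)
  cricket_x <- cricket_y <- numeric(n)
  approach_state <- logical(n)

  margin <- 4
  rand_pos <- function() c(stats::runif(1, 5, p$arena_cm[1] - 5),
                           stats::runif(1, 5, p$arena_cm[2] - 5))
  pos <- c(p$arena_cm[1] / 2, p$arena_cm[2] / 2)
  ck <- rand_pos()
  hd <- stats::runif(1, -180, 180)
  turn <- 0
  spd <- p$explore_speed_mean
  pt <- 0
  os <- 0
  state <- "explore"
  bout_i <- 1L
  bout_end <- u_bout[bout_i] * p$rate

  for (i in seq_len(n)) {
    bearing <- rad2deg(atan2(ck[2] - pos[2], ck[1] - pos[1]))
    if (state == "explore") {
      # wander; near a wall, steer only while the heading points strongly
      # outward (just enough to curve back inside)
      turn <- ou_step(turn, 0, a_turn, p$explore_turn_sd, eps_turn[i])
      turn_cmd <- turn
      near_wall <- pos[1] < margin || pos[1] > p$arena_cm[1] - margin ||
        pos[2] < margin || pos[2] > p$arena_cm[2] - margin
      if (near_wall) {
        to_center <- rad2deg(atan2(p$arena_cm[2] / 2 - pos[2],
                                   p$arena_cm[1] / 2 - pos[1]))
        err <- wrap_angle(to_center - hd)
        if (abs(err) > 60) {
          turn_cmd <- clamp(3 * (err - 60 * sign(err)), -120, 120)
        }
      }
      spd <- ou_step(spd, p$explore_speed_mean, a_speed, p$explore_speed_sd,
                     eps_speed[i])
      pt <- ou_step(pt, 0, a_pitch, p$pitch_sd_explore, eps_pitch[i])
      bout_end <- bout_end - 1
      if (bout_end <= 0) state <- "approach"
      if (u_capture[i] < p$cricket_relocation_hz * dt) ck <- rand_pos()
    } else {
      turn <- ou_step(turn, 0, a_turn, p$explore_turn_sd, eps_turn[i])
      turn_cmd <- clamp(p$approach_turn_gain * wrap_angle(bearing - hd),
                        -p$approach_turn_max, p$approach_turn_max) +
        0.3 * turn
      spd <- ou_step(spd, p$approach_speed_mean, a_speed, p$approach_speed_sd,
                     eps_speed[i])
      pt <- ou_step(pt, 0, a_pitch, p$pitch_sd_approach, eps_pitch[i])
      if (sqrt(sum((ck - pos)^2)) < p$capture_radius_cm) {
        ck <- rand_pos()
        state <- "explore"
        bout_i <- bout_i + 1L
        bout_end <- u_bout[bout_i] * p$rate
      }
    }
    spd <- max(spd, 0)
    hd <- hd + turn_cmd * dt
    pos <- pos + spd * dt * c(cos(deg2rad(hd)), sin(deg2rad(hd)))
    pos <- clamp(pos, 0.5, p$arena_cm - 0.5)
    os <- ou_step(os, 0, a_osc, p$yaw_osc_sd, eps_osc[i])
    x[i] <- pos[1]; y[i] <- pos[2]
    heading[i] <- hd; osc[i] <- os
    pitch[i] <- pt; speed[i] <- spd
    cricket_x[i] <- ck[1]; cricket_y[i] <- ck[2]
    approach_state[i] <- state == "approach"
  }
  yaw_u <- heading + osc   # unwrapped head yaw, degrees

  ## ---- eyes: VOR with recentering saccades --------------------------------
  set.seed(sub_seeds[2])
  verg_noise <- stats::rnorm(n, 0, p$vergence_noise_sd)
  eps_ev <- stats::rnorm(n)
  a_ev <- exp(-dt / p$eye_v_tau_s)

  theta_mean <- numeric(n)
  sacc_onsets <- integer(0)
  sacc_offsets <- integer(0)
  remaining <- 0L
  step <- 0
  for (i in 2:n) {
    if (remaining > 0L) {
      theta_mean[i] <- theta_mean[i - 1] + step
      remaining <- remaining - 1L
      if (remaining == 0L) sacc_offsets <- c(sacc_offsets, i)
    } else {
      theta_mean[i] <- theta_mean[i - 1] - p$vor_gain * (yaw_u[i] - yaw_u[i - 1])
      # trigger on eccentricity relative to the slow heading trend: the
      # fast scanning oscillation is VOR-imaged onto the eye and reverts by
      # itself, so triggering on the raw eye position would fire runs of
      # spurious saccades at every oscillation extreme
      ecc <- theta_mean[i] + p$vor_gain * osc[i]
      # a recentering movement is only launched when the eye itself is
      # substantially deviated, not when the fast oscillation happens to
      # carry it through center at the moment the trend crosses threshold
      if (is.finite(p$saccade_trigger_deg) &&
          abs(ecc) > p$saccade_trigger_deg &&
          abs(theta_mean[i]) > 0.45 * p$saccade_trigger_deg && i < n) {
        # reset to zero over the next saccade_duration_frames frames
        sacc_onsets <- c(sacc_onsets, i + 1L)
        step <- -theta_mean[i] / p$saccade_duration_frames
        remaining <- as.integer(p$saccade_duration_frames)
      }
    }
  }
  # a reset still in progress at the end of the session
  if (remaining > 0L) sacc_offsets <- c(sacc_offsets, n)

  theta_v <- numeric(n)
  for (i in 2:n) theta_v[i] <- ou_step(theta_v[i - 1], 0, a_ev, p$eye_v_sd, eps_ev[i])
  vergence <- p$pitch_vergence_slope * pitch + verg_noise
  theta_r <- theta_mean + vergence / 2
  theta_l <- theta_mean - vergence / 2
  gaze <- yaw_u + theta_mean

  ## ---- measurement noise on exported angle channels -----------------------
  set.seed(sub_seeds[3])
  s <- p$sigma_meas_deg
  theta_r_meas <- theta_r + stats::rnorm(n, 0, s)
  theta_l_meas <- theta_l + stats::rnorm(n, 0, s)
  yaw_meas <- wrap_angle(yaw_u + stats::rnorm(n, 0, s))
  pitch_meas <- pitch + stats::rnorm(n, 0, s)
  if (p$sigma_pos_cm > 0) {
    x_meas <- x + stats::rnorm(n, 0, p$sigma_pos_cm)
    y_meas <- y + stats::rnorm(n, 0, p$sigma_pos_cm)
  } else {
    x_meas <- x; y_meas <- y
  }

  ## ---- derived truth channels and ground-truth events ---------------------
  spd_true <- compute_speed(x, y, p$rate)
  tg <- target_geometry(tibble::tibble(x = x, y = y, yaw = wrap_angle(yaw_u)),
                        cricket_x, cricket_y, p$rate)
  approaches <- detect_approaches(spd_true, tg$azimuth, tg$range_rate, p$rate,
                                  merge_gap_ms = 0, min_duration_ms = 0)

  sacc_truth <- tibble::tibble(
    onset_frame = sacc_onsets[seq_along(sacc_offsets)],
    offset_frame = sacc_offsets,
    onset = (sacc_onsets[seq_along(sacc_offsets)] - 1) / p$rate,
    amplitude = gaze[sacc_offsets] -
      gaze[pmax(1L, sacc_onsets[seq_along(sacc_offsets)] - 1L)]
  )
  sac_mask <- rep(FALSE, n)
  for (k in seq_len(nrow(sacc_truth))) {
    sac_mask[sacc_truth$onset_frame[k]:sacc_truth$offset_frame[k]] <- TRUE
  }
  fix_runs <- true_runs(!sac_mask)
  fix_truth <- tibble::tibble(
    start_frame = as.integer(fix_runs[, 1]),
    end_frame = as.integer(fix_runs[, 2]),
    duration_ms = (fix_runs[, 2] - fix_runs[, 1] + 1) * 1000 / p$rate
  )

  kin <- tibble::tibble(
    frame = seq_len(n) - 1L,
    t = (seq_len(n) - 1) / p$rate,
    x = x_meas, y = y_meas,
    speed = spd_true,
    yaw = wrap_angle(yaw_u), yaw_unwrapped = yaw_u,
    pitch = pitch,
    cricket_x = cricket_x, cricket_y = cricket_y,
    distance = tg$distance, azimuth = tg$azimuth, range_rate = tg$range_rate,
    theta_r = theta_r, theta_l = theta_l, theta_v = theta_v,
    gaze = gaze,
    approach = approach_state,
    theta_r_meas = theta_r_meas, theta_l_meas = theta_l_meas,
    yaw_meas = yaw_meas, pitch_meas = pitch_meas
  )
  structure(list(kinematics = kin,
                 truth = list(saccades = sacc_truth, fixations = fix_truth,
                              approaches = approaches),
                 params = p),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %.0f s at %g Hz (%d frames), %d true saccades, %d approach intervals\n",
    x$params$duration_s, x$params$rate, nrow(x$kinematics),
    nrow(x$truth$saccades),
    sum(x$truth$approaches$label == "approach")))
  invisible(x)
}

#' Forward-project eye angles to pupil ellipses
#'
#' Implements the spherical-eye camera model used for calibration: when the
#' eye points along the camera axis the pupil is circular; as it rotates
#' the imaged pupil center shifts by `R * (sin(theta_h), sin(theta_v))` and
#' the circle flattens into an ellipse with ellipticity equal to the cosine
#' of the total angular offset, major axis perpendicular to the
#' displacement from the camera-axis center.
#'
#' @param theta_h,theta_v Eye angles, degrees (|theta| < 90).
#' @param cal List with `cx`, `cy` (camera-axis center, px) and `R` (scale
#'   factor, px).
#' @param pupil_radius_px Pupil radius when circular (semi-major axis), px;
#'   default half the rotation radius, the approximate anatomical ratio of
#'   pupil to eyeball radius in the mouse.
#' @param edge_points If TRUE, also sample `n_edge` points per frame on the
#'   ellipse at equal parametric angles.
#' @param n_edge Number of edge points.
#' @param noise_px SD of iid Gaussian pixel noise added to the edge points.
#' @return Tibble with `frame`, `cx`, `cy`, `a`, `b`, `phi`, `e`; when
#'   `edge_points` is TRUE the long point tibble (`frame`, `point`, `x`,
#'   `y`, `likelihood`) is attached as attribute `points`.
#' @export
project_pupil <- function(theta_h, theta_v, cal = list(cx = 320, cy = 240, R = 60),
                          pupil_radius_px = 30, edge_points = FALSE,
                          n_edge = 8, noise_px = 0) {
  stopifnot(length(theta_h) == length(theta_v), cal$R > 0)
  sh <- sin(deg2rad(theta_h))
  sv <- sin(deg2rad(theta_v))
  s2 <- clamp(sh^2 + sv^2, 0, 1)
  e <- sqrt(1 - s2)
  px <- cal$cx + cal$R * sh
  py <- cal$cy + cal$R * sv
  # major axis perpendicular to the displacement from the camera-axis center
  phi <- ifelse(s2 > 0, rad2deg(atan2(sv, sh)) + 90, 0)
  phi <- ifelse(phi > 90, phi - 180, phi)
  phi <- ifelse(phi <= -90, phi + 180, phi)
  ell <- tibble::tibble(frame = seq_along(theta_h) - 1L,
                        cx = px, cy = py,
                        a = pupil_radius_px, b = pupil_radius_px * e,
                        phi = phi, e = e)
  if (edge_points) {
    psi <- 2 * pi * (seq_len(n_edge) - 1) / n_edge
    mdir <- cbind(cos(deg2rad(phi)), sin(deg2rad(phi)))       # major axis
    ndir <- cbind(-mdir[, 2], mdir[, 1])                      # minor axis
    pts <- lapply(seq_len(n_edge), function(k) {
      tibble::tibble(
        frame = ell$frame,
        point = sprintf("pupil_%d", k),
        x = px + ell$a * cos(psi[k]) * mdir[, 1] + ell$b * sin(psi[k]) * ndir[, 1],
        y = py + ell$a * cos(psi[k]) * mdir[, 2] + ell$b * sin(psi[k]) * ndir[, 2],
        likelihood = 1
      )
    })
    pts <- dplyr::arrange(dplyr::bind_rows(pts), .data$frame, .data$point)
    if (noise_px > 0) {
      pts$x <- pts$x + stats::rnorm(nrow(pts), 0, noise_px)
      pts$y <- pts$y + stats::rnorm(nrow(pts), 0, noise_px)
    }
    attr(ell, "points") <- pts
  }
  ell
}

# default 8-point head landmark constellation, cm, head frame (+x = nose)
default_head_template <- function() {
  tibble::tibble(
    point = c("nose", "head_center", "left_ear", "right_ear",
              "left_eye", "right_eye", "implant_left", "implant_right"),
    x = c(2.5, 0, -0.5, -0.5, 1.2, 1.2, -1.2, -1.2),
    y = c(0, 0, 1.1, -1.1, 0.8, -0.8, 0.6, -0.6)
  )
}

#' Export a synthetic session as raw-style tracker and IMU files
#'
#' Writes the file bundle the analysis pipeline starts from, so the whole
#' chain can be exercised end to end: an overhead landmark CSV (the head
#' constellation rendered from the true pose, plus two cricket points), one
#' pupil landmark CSV per eye (edge points from the forward projection
#' model), a 50 Hz IMU CSV (pitch re-encoded as gravity components, yaw
#' rate as a gyroscope channel, in volts), and a ground-truth JSON.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @param eye_cal Projection model for both eye cameras: list with `cx`,
#'   `cy`, `R` in pixels.
#' @param pupil_radius_px Circular pupil radius, px.
#' @param edge_noise_px Pixel noise on pupil edge points.
#' @param head_noise_cm Noise on overhead head/cricket landmarks, cm.
#' @param accel_gain (m/s^2)/V encoding gain for the accelerometer
#'   channels; the written voltages are `a / accel_gain`.
#' @param gyro_gain (rad/s)/V encoding gain for the gyroscope channels.
#' @param imu_rate IMU sampling rate, Hz.
#' @param imu_noise_v Voltage noise SD on IMU channels.
#' @return Named list of written file paths.
#' @export
export_raw_style <- function(session, dir,
                             eye_cal = list(cx = 320, cy = 240, R = 60),
                             pupil_radius_px = 30, edge_noise_px = 0.5,
                             head_noise_cm = 0,
                             accel_gain = 4.905, gyro_gain = 5,
                             imu_rate = 50, imu_noise_v = 0) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- session$kinematics
  p <- session$params
  set.seed(p$seed + 17L)  # export-stage noise stream

  ## overhead camera: head constellation + cricket
  tpl <- default_head_template()
  yawr <- deg2rad(kin$yaw_unwrapped)
  head_pts <- lapply(seq_len(nrow(tpl)), function(k) {
    tibble::tibble(
      frame = kin$frame, point = tpl$point[k],
      x = kin$x + tpl$x[k] * cos(yawr) - tpl$y[k] * sin(yawr),
      y = kin$y + tpl$x[k] * sin(yawr) + tpl$y[k] * cos(yawr),
      likelihood = 1
    )
  })
  cricket_pts <- list(
    tibble::tibble(frame = kin$frame, point = "cricket_head",
                   x = kin$cricket_x, y = kin$cricket_y, likelihood = 1),
    tibble::tibble(frame = kin$frame, point = "cricket_body",
                   x = kin$cricket_x - 0.5, y = kin$cricket_y, likelihood = 1)
  )
  overhead <- dplyr::bind_rows(c(head_pts, cricket_pts))
  if (head_noise_cm > 0) {
    overhead$x <- overhead$x + stats::rnorm(nrow(overhead), 0, head_noise_cm)
    overhead$y <- overhead$y + stats::rnorm(nrow(overhead), 0, head_noise_cm)
  }
  f_overhead <- file.path(dir, "overhead.csv")
  write_tracker_csv(overhead, f_overhead, scorer = "synthetic")

  ## eye cameras: pupil edge points from the projection model
  eye_files <- character(2)
  for (side in c("right", "left")) {
    th <- if (side == "right") kin$theta_r else kin$theta_l
    proj <- project_pupil(th, kin$theta_v, eye_cal,
                          pupil_radius_px = pupil_radius_px,
                          edge_points = TRUE, noise_px = edge_noise_px)
    f <- file.path(dir, sprintf("%s_eye.csv", side))
    write_tracker_csv(attr(proj, "points"), f, scorer = "synthetic")
    eye_files[if (side == "right") 1 else 2] <- f
  }

  ## IMU at its own (lower) rate, re-encoded as voltages
  t_imu <- target_grid(0, max(kin$t), imu_rate)
  pitch_i <- resample_series(kin$t, kin$pitch, t_imu)
  yaw_rate_i <- resample_series(kin$t, compute_velocity(kin$yaw_unwrapped, p$rate),
                                t_imu)
  g <- 9.81
  af <- g * sin(deg2rad(pitch_i))
  al <- rep(0, length(t_imu))
  ad <- sqrt(pmax(0, g^2 - af^2))
  imu <- tibble::tibble(
    t = t_imu,
    ax = af / accel_gain, ay = al / accel_gain, az = ad / accel_gain,
    gx = 0, gy = 0, gz = deg2rad(yaw_rate_i) / gyro_gain
  )
  if (imu_noise_v > 0) {
    for (col in c("ax", "ay", "az", "gx", "gy", "gz")) {
      imu[[col]] <- imu[[col]] + stats::rnorm(nrow(imu), 0, imu_noise_v)
    }
  }
  f_imu <- file.path(dir, "imu.csv")
  readr::write_csv(imu, f_imu)

  ## ground truth
  f_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    saccades = session$truth$saccades,
    fixations = session$truth$fixations,
    approaches = tibble::as_tibble(session$truth$approaches),
    calibration = c(eye_cal, pupil_radius_px = pupil_radius_px),
    imu = list(accel_gain = accel_gain, gyro_gain = gyro_gain, rate = imu_rate),
    head_template = tpl,
    params = session$params[vapply(session$params, is.numeric, logical(1))]
  ), f_truth, auto_unbox = TRUE, digits = NA)

  list(overhead = f_overhead, right_eye = eye_files[1], left_eye = eye_files[2],
       imu = f_imu, ground_truth = f_truth)
}

# write a long landmark tibble in the three-header-row tracker dialect
write_tracker_csv <- function(points, path, scorer = "synthetic") {
  pts <- unique(points$point)
  frames <- sort(unique(points$frame))
  wide <- matrix(NA_real_, length(frames), 3 * length(pts))
  fidx <- match(points$frame, frames)
  pidx <- match(points$point, pts)
  wide[cbind(fidx, 3 * (pidx - 1) + 1)] <- points$x
  wide[cbind(fidx, 3 * (pidx - 1) + 2)] <- points$y
  wide[cbind(fidx, 3 * (pidx - 1) + 3)] <- points$likelihood
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, 3 * length(pts))), collapse = ","),
    paste(c("bodyparts", rep(pts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(pts))), collapse = ",")
  ), con)
  utils::write.table(cbind(frames, wide), con, sep = ",", col.names = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
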