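#' Fit an ellipse to pupil edge points
#'
#' Direct algebraic least-squares conic fit with the ellipse constraint
#' (Fitzgibbon's method in the numerically stable Halir--Flusser form).
#' This is the standard closed-form estimator for the eight pupil-edge
#' points produced by markerless tracking: it is deterministic and needs no
#' initial guess.
#'
#' @param points Data frame or matrix with columns `x`, `y` (pixels) and
#'   optionally `likelihood`; points with `likelihood` below
#'   `conf_threshold` (or NA coordinates) are dropped before fitting.
#' @param conf_threshold Minimum confidence for a point to be used.
#' @return An object of class `pupil_ellipse`: list with `cx`, `cy`
#'   (center, px), `a`, `b` (semi-major/minor, px), `phi` (major-axis
#'   direction, degrees in (-90, 90]), `e` (ellipticity b/a), `n_points`.
#' @export
fit_pupil_ellipse <- function(points, conf_threshold = 0.9) {
  points <- as.data.frame(points)
  x <- points$x
  y <- points$y
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(points$likelihood)) keep <- keep & points$likelihood >= conf_threshold
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 5) stop("ellipse fit needs at least 5 valid points", call. = FALSE)
  # center and scale for conditioning
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s < .Machine$double.eps) {
    stop("degenerate point configuration for ellipse fit", call. = FALSE)
  }
  xs <- (x - mx) / s
  ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("degenerate (collinear) points for ellipse fit", call. = FALSE)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inverse of constraint matrix [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution (degenerate or hyperbolic fit)", call. = FALSE)
  a1 <- evec[, ok[1]]
  coef <- c(a1, Tm %*% a1)  # A B C D E F in scaled frame
  # undo the normalisation: substitute xs=(x-mx)/s, ys=(y-my)/s
  A <- coef[1] / s^2
  B <- coef[2] / s^2
  C <- coef[3] / s^2
  D <- coef[4] / s - (2 * coef[1] * mx + coef[2] * my) / s^2
  E <- coef[5] / s - (2 * coef[3] * my + coef[2] * mx) / s^2
  F <- coef[6] - coef[4] * mx / s - coef[5] * my / s +
    (coef[1] * mx^2 + coef[2] * mx * my + coef[3] * my^2) / s^2
  conic_to_ellipse(c(A, B, C, D, E, F), n_points = length(x))
}

# convert conic coefficients (A,B,C,D,E,F) to geometric parameters
conic_to_ellipse <- function(k, n_points = NA_integer_) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  det2 <- 4 * A * C - B^2
  if (det2 <= 0) stop("conic is not an ellipse", call. = FALSE)
  cx <- (B * E - 2 * C * D) / det2
  cy <- (B * D - 2 * A * E) / det2
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values            # decreasing
  axes2 <- -F0 / lam
  if (any(axes2 <= 0)) stop("conic is not a real ellipse", call. = FALSE)
  i_major <- which.max(axes2)
  a <- sqrt(axes2[i_major])
  b <- sqrt(min(axes2))
  v <- eg$vectors[, i_major]  # major-axis direction
  phi <- rad2deg(atan2(v[2], v[1]))
  if (phi <= -90) phi <- phi + 180
  if (phi > 90) phi <- phi - 180
  structure(list(cx = cx, cy = cy, a = a, b = b, phi = phi, e = b / a,
                 n_points = n_points),
            class = "pupil_ellipse")
}

#' @export
print.pupil_ellipse <- function(x, ...) {
  cat(sprintf(
    "<pupil_ellipse> center (%.2f, %.2f) px, a = %.2f, b = %.2f px, phi = %.1f deg, e = %.3f\n",
    x$cx, x$cy, x$a, x$b, x$phi, x$e))
  invisible(x)
}

#' Fit pupil ellipses for every frame of a landmark table
#'
#' @param landmarks Long tibble as returned by [read_tracker_landmarks()]
#'   (columns `frame`, `t`, `point`, `x`, `y`, `likelihood`) holding the
#'   pupil-edge points of one eye camera.
#' @param conf_threshold Minimum point confidence.
#' @return Tibble with one row per frame: `frame`, `t`, `cx`, `cy`, `a`,
#'   `b`, `phi`, `e`, `valid`. Frames whose fit fails (fewer than 5 valid
#'   points, collinear, or hyperbolic) are flagged invalid with NA
#'   parameters.
#' @export
fit_pupil_ellipses <- function(landmarks, conf_threshold = 0.9) {
  landmarks |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_modify(function(d, key) {
      t0 <- if ("t" %in% names(d)) d$t[1] else NA_real_
      fit <- tryCatch(fit_pupil_ellipse(d, conf_threshold), error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(t = t0, cx = NA_real_, cy = NA_real_, a = NA_real_,
                       b = NA_real_, phi = NA_real_, e = NA_real_, valid = FALSE)
      } else {
        tibble::tibble(t = t0, cx = fit$cx, cy = fit$cy, a = fit$a, b = fit$b,
                       phi = fit$phi, e = fit$e, valid = TRUE)
      }
    }) |>
    dplyr::ungroup()
}

# frames eligible for calibration: valid and sufficiently elliptical
select_calibration_frames <- function(ellipses, min_eccentricity) {
  ok <- !is.na(ellipses$e) & ellipses$e <= 1 - min_eccentricity
  if ("valid" %in% names(ellipses)) ok <- ok & ellipses$valid
  ellipses[ok, , drop = FALSE]
}

#' Estimate the camera-axis center from pupil ellipse geometry
#'
#' Under the spherical-eye projection model the pupil appears circular when
#' the eye points along the camera axis, and as it rotates away the imaged
#' pupil flattens into an ellipse whose major axis is perpendicular to the
#' vector from the pupil center to the camera-axis center. Each
#' sufficiently elliptical frame therefore contributes one linear
#' constraint `m_i . c = m_i . p_i` (with `m_i` the major-axis unit vector
#' and `p_i` the pupil center); the stack is solved by least squares.
#'
#' @param ellipses Per-frame ellipse tibble (see [fit_pupil_ellipses()]).
#' @param min_eccentricity Minimum 1 - e for a frame to constrain the
#'   solution (default 0.01, i.e. ellipticity at most 0.99, roughly 8
#'   degrees off axis).
#' @param max_condition Reject constraint sets more ill-conditioned than
#'   this (near-parallel major axes).
#' @return Named numeric `c(x, y)` in pixels with attributes `residual`
#'   (RMS constraint residual, px) and `n_frames`.
#' @export
estimate_camera_center <- function(ellipses, min_eccentricity = 0.01,
                                   max_condition = 1e6) {
  sel <- select_calibration_frames(ellipses, min_eccentricity)
  if (nrow(sel) < 2) {
    stop("calibration needs at least 2 frames with sufficient ellipticity",
         call. = FALSE)
  }
  phi <- deg2rad(sel$phi)
  M <- cbind(cos(phi), sin(phi))
  b <- M[, 1] * sel$cx + M[, 2] * sel$cy
  sv <- svd(M)$d
  if (sv[2] < .Machine$double.eps || sv[1] / sv[2] > max_condition) {
    stop("camera-center constraints are near-parallel; rotate-rich data needed",
         call. = FALSE)
  }
  cc <- qr.solve(M, b)
  res <- sqrt(mean((M %*% cc - b)^2))
  out <- c(x = cc[1], y = cc[2])
  attr(out, "residual") <- res
  attr(out, "n_frames") <- nrow(sel)
  out
}

#' Estimate the pixel-to-angle scale factor
#'
#' Under the projection model the ellipticity of the pupil encodes the
#' rotation away from the camera axis: `e_i = cos(theta_i)` while the pupil
#' center is displaced by `|p_i - c| = R sin(theta_i)`. Eliminating
#' `theta_i` gives `|p_i - c| = R sqrt(1 - e_i^2)`, so `R` is the
#' least-squares slope through the origin of displacement against
#' `sqrt(1 - e^2)`.
#'
#' The default frame selection is stricter than for the camera-axis center
#' (ellipticity at most 0.9, roughly 26 degrees off axis): near circularity
#' the `sqrt(1 - e^2)` term is ill-conditioned — its sensitivity to
#' point-level noise diverges — and weakly elliptical frames bias the slope
#' downward. When fewer than `min_frames` frames pass the strict cut the
#' selection falls back to the center-estimation threshold.
#'
#' @param ellipses Per-frame ellipse tibble.
#' @param center Camera-axis center `c(x, y)` in pixels.
#' @param min_eccentricity Minimum 1 - e for a frame to enter the scale
#'   regression (default 0.1).
#' @param fallback_eccentricity,min_frames Relaxed threshold used when too
#'   few frames pass the strict one.
#' @return Scale factor R in pixels (the effective rotation radius).
#' @export
estimate_scale <- function(ellipses, center, min_eccentricity = 0.1,
                           fallback_eccentricity = 0.01, min_frames = 50) {
  sel <- select_calibration_frames(ellipses, min_eccentricity)
  if (nrow(sel) < min_frames) {
    sel <- select_calibration_frames(ellipses,
                                     min(min_eccentricity,
                                         fallback_eccentricity))
  }
  if (nrow(sel) < 1) stop("no frames with sufficient ellipticity", call. = FALSE)
  s <- sqrt(pmax(0, 1 - sel$e^2))
  if (all(s < .Machine$double.eps)) {
    stop("all selected frames circular; scale is unidentifiable", call. = FALSE)
  }
  d <- sqrt((sel$cx - center[[1]])^2 + (sel$cy - center[[2]])^2)
  sum(d * s) / sum(s^2)
}

#' Calibrate one eye camera from its pupil ellipse sequence
#'
#' Runs [estimate_camera_center()] then [estimate_scale()] and packages the
#' result with diagnostics. [tidy()] and [glance()] methods are provided.
#'
#' @inheritParams estimate_camera_center
#' @param scale_min_eccentricity Stricter selection for the scale step (see
#'   [estimate_scale()]).
#' @return Object of class `eye_calibration`: list with `cx`, `cy`, `R`
#'   (pixels), `n_frames_used`, `residual` (px), `min_eccentricity`,
#'   `scale_min_eccentricity`.
#' @export
calibrate_eye <- function(ellipses, min_eccentricity = 0.01,
                          scale_min_eccentricity = 0.1,
                          max_condition = 1e6) {
  if (nrow(ellipses) == 0) stop("empty ellipse sequence", call. = FALSE)
  cc <- estimate_camera_center(ellipses, min_eccentricity, max_condition)
  R <- estimate_scale(ellipses, cc, scale_min_eccentricity,
                      fallback_eccentricity = min_eccentricity)
  structure(list(cx = unname(cc[1]), cy = unname(cc[2]), R = R,
                 n_frames_used = attr(cc, "n_frames"),
                 residual = attr(cc, "residual"),
                 min_eccentricity = min_eccentricity,
                 scale_min_eccentricity = scale_min_eccentricity),
            class = "eye_calibration")
}

#' @export
print.eye_calibration <- function(x, ...) {
  cat(sprintf(
    "<eye_calibration> camera-axis center (%.2f, %.2f) px, R = %.2f px\n  %d frames used, constraint residual %.3g px\n",
    x$cx, x$cy, x$R, x$n_frames_used, x$residual))
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param cal An `eye_calibration` object.
#' @param path Output file path.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert pupil center positions to angular eye position
#'
#' Inverts the spherical projection: `theta_h = asin((p_x - c_x)/R)` and
#' `theta_v = asin((p_y - c_y)/R)`, in degrees. Displacements numerically
#' outside the model (`|p - c| > R` componentwise) are clipped to +/-90
#' degrees and flagged. Per-eye sign factors map the camera image frame
#' into a shared head frame in which rightward is positive for both eyes.
#'
#' @param pupils Tibble with pupil centers `cx`, `cy` (e.g. from
#'   [fit_pupil_ellipses()]) and optionally `t`, `frame`, `valid`.
#' @param cal An `eye_calibration` object (or list with `cx`, `cy`, `R`).
#' @param sign_h,sign_v +1 or -1: orientation of the image axes relative to
#'   the head frame for this eye.
#' @return Tibble with `theta_h`, `theta_v` (degrees), `valid`, `clipped`
#'   (plus `t`/`frame` carried through when present).
#' @export
pupil_to_angle <- function(pupils, cal, sign_h = 1, sign_v = 1) {
  stopifnot(cal$R > 0)
  uh <- (pupils$cx - cal$cx) / cal$R
  uv <- (pupils$cy - cal$cy) / cal$R
  clipped <- (!is.na(uh) & abs(uh) > 1) | (!is.na(uv) & abs(uv) > 1)
  if (any(clipped, na.rm = TRUE)) {
    warning("pupil displacement exceeds calibration radius for ",
            sum(clipped, na.rm = TRUE), " frame(s); clipped")
  }
  th <- sign_h * rad2deg(asin(clamp(uh, -1, 1)))
  tv <- sign_v * rad2deg(asin(clamp(uv, -1, 1)))
  valid <- !is.na(th) & !is.na(tv)
  if ("valid" %in% names(pupils)) valid <- valid & pupils$valid
  out <- tibble::tibble(theta_h = th, theta_v = tv, valid = valid,
                        clipped = clipped & valid)
  keep <- intersect(c("frame", "t"), names(pupils))
  if (length(keep)) out <- dplyr::bind_cols(pupils[keep], out)
  out
}

#' Re-reference eye angles to the session mean
#'
#' Central eye position (0 degrees) is defined as the average pupil
#' location for each eye across the recording, so the per-component mean
#' over valid samples is subtracted.
#'
#' @param eyes Tibble with `theta_h`, `theta_v` and optionally `valid`.
#' @return The same tibble with `theta_h`, `theta_v` centered.
#' @export
center_eye_positions <- function(eyes) {
  valid <- if ("valid" %in% names(eyes)) eyes$valid else rep(TRUE, nrow(eyes))
  valid <- valid & !is.na(eyes$theta_h) & !is.na(eyes$theta_v)
  if (!any(valid)) stop("no valid samples to center on", call. = FALSE)
  dplyr::mutate(eyes,
                theta_h = .data$theta_h - mean(.data$theta_h[valid]),
                theta_v = .data$theta_v - mean(.data$theta_v[valid]))
}

#' Estimate eye-position measurement error from stationary periods
#'
#' When the animal is still (speed below `speed_threshold` and
#' frame-to-frame head rotation below `rot_threshold`) eye movements are
#' expected to be minimal, so residual frame-to-frame variability of
#' horizontal eye position bounds the measurement error. The default
#' estimator is the standard deviation of frame-to-frame differences
#' divided by sqrt(2) (unbiased for iid noise on a constant signal); the
#' alternative pools the within-run standard deviation of position itself.
#'
#' @param theta_h Horizontal eye position, degrees.
#' @param speed Speed series, cm/s, same length.
#' @param head_rot Frame-to-frame head rotation, degrees per frame, same
#'   length.
#' @param speed_threshold,rot_threshold Stationarity bounds (cm/s, deg).
#' @param method `"diff"` (default) or `"window"`.
#' @return Estimated measurement error in degrees.
#' @export
estimate_eye_measurement_error <- function(theta_h, speed, head_rot,
                                           speed_threshold = 1,
                                           rot_threshold = 1,
                                           method = c("diff", "window")) {
  method <- match.arg(method)
  n <- length(theta_h)
  stopifnot(length(speed) == n, length(head_rot) == n)
  mask <- !is.na(theta_h) & !is.na(speed) & !is.na(head_rot) &
    speed < speed_threshold & abs(head_rot) < rot_threshold
  if (!any(mask)) stop("no stationary samples", call. = FALSE)
  if (method == "diff") {
    pair <- mask[-n] & mask[-1]
    if (sum(pair) < 2) stop("too few stationary frame pairs", call. = FALSE)
    d <- diff(theta_h)[pair]
    stats::sd(d) / sqrt(2)
  } else {
    runs <- true_runs(mask)
    runs <- runs[runs[, 2] - runs[, 1] >= 1, , drop = FALSE]
    if (nrow(runs) == 0) stop("no stationary runs of length >= 2", call. = FALSE)
    ss <- 0; df <- 0
    for (i in seq_len(nrow(runs))) {
      v <- theta_h[runs[i, 1]:runs[i, 2]]
      ss <- ss + sum((v - mean(v))^2)
      df <- df + length(v) - 1
    }
    sqrt(ss / df)
  }
}
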