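#' Vergence angle of the two eyes
#'
#' Vergence is the difference in horizontal position of the two eyes,
#' `V = theta_R - theta_L`, with both eyes expressed rightward-positive in
#' the shared head frame. Negative values mean the eyes are converged
#' (rotated nasally), positive diverged.
#'
#' @param theta_r,theta_l Horizontal eye position of right and left eye
#'   (degrees), equal length.
#' @return Vergence series in degrees.
#' @export
compute_vergence <- function(theta_r, theta_l) {
  if (length(theta_r) != length(theta_l)) {
    stop("eye series have mismatched lengths", call. = FALSE)
  }
  theta_r - theta_l
}

#' Mean (conjugate) horizontal eye position
#'
#' Averaging the two eyes removes vergence shifts and isolates their
#' coordinated movement: `E = (theta_R + theta_L)/2`. Invalid samples in
#' either eye propagate.
#'
#' @inheritParams compute_vergence
#' @return Mean eye position series in degrees.
#' @export
compute_mean_eye <- function(theta_r, theta_l) {
  if (length(theta_r) != length(theta_l)) {
    stop("eye series have mismatched lengths", call. = FALSE)
  }
  (theta_r + theta_l) / 2
}

#' Gaze direction as head plus eye
#'
#' Gaze is the sum of head yaw and mean horizontal eye position,
#' `G = H + E`, computed on the unwrapped line so that velocity estimates
#' never see spurious 360 degree seams; wrap only at export.
#'
#' @param yaw Head yaw series (degrees; wrapped input is unwrapped first).
#' @param mean_eye Mean eye position (degrees).
#' @return Unwrapped gaze series in degrees.
#' @export
compute_gaze <- function(yaw, mean_eye) {
  unwrap_angle(yaw) + mean_eye
}

#' Central-difference velocity
#'
#' `v[i] = (x[i+1] - x[i-1]) * rate / 2`, with one-sided differences at the
#' ends. Symmetric, so a single-frame step spreads over the two
#' neighbouring samples.
#'
#' @param x Series in degrees (or any unit).
#' @param rate Sampling rate, Hz.
#' @return Velocity series, unit/s.
#' @export
compute_velocity <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("velocity needs at least 3 samples", call. = FALSE)
  v <- rep(NA_real_, n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v
}

#' Classify samples as compensatory or saccadic
#'
#' Gaze samples with absolute gaze velocity strictly above the threshold
#' (default 180 deg/s, chosen from the bimodal gaze-velocity distribution)
#' are saccadic; all other valid samples are compensatory. A velocity
#' exactly at the threshold is compensatory.
#'
#' @param gaze_velocity Gaze velocity series, deg/s.
#' @param threshold Velocity threshold, deg/s (> 0).
#' @return Character vector with values `"compensatory"`, `"saccadic"`, or
#'   NA for invalid samples.
#' @export
classify_gaze_samples <- function(gaze_velocity, threshold = 180) {
  stopifnot(threshold > 0)
  out <- rep(NA_character_, length(gaze_velocity))
  ok <- !is.na(gaze_velocity)
  out[ok] <- ifelse(abs(gaze_velocity[ok]) > threshold, "saccadic", "compensatory")
  out
}

#' Segment fixations from sample labels
#'
#' Maximal runs of compensatory samples at least `min_duration_ms` long
#' become fixations.
#'
#' @param labels Per-sample labels from [classify_gaze_samples()].
#' @param rate Sampling rate, Hz.
#' @param min_duration_ms Minimum fixation duration (ms).
#' @return Tibble of class `fixation_set`: `start_frame`, `end_frame`
#'   (inclusive sample indices), `start`, `end` (seconds, half-open),
#'   `duration_ms`.
#' @export
segment_fixations <- function(labels, rate, min_duration_ms = 50) {
  runs <- true_runs(labels == "compensatory")
  if (nrow(runs)) {
    len <- runs[, 2] - runs[, 1] + 1
    keep <- len * 1000 / rate >= min_duration_ms
    runs <- runs[keep, , drop = FALSE]
  }
  out <- tibble::tibble(
    start_frame = as.integer(runs[, 1]),
    end_frame = as.integer(runs[, 2]),
    start = (runs[, 1] - 1) / rate,
    end = runs[, 2] / rate,
    duration_ms = (runs[, 2] - runs[, 1] + 1) * 1000 / rate
  )
  class(out) <- c("fixation_set", class(tibble::tibble()))
  attr(out, "rate") <- rate
  out
}

#' Detect saccades from sample labels and the gaze trace
#'
#' Each maximal saccadic run becomes one saccade; runs separated by at most
#' `merge_gap_samples` compensatory samples are merged first, because the
#' central-difference velocity smears a single-frame gaze step over its
#' neighbours. Onset is the first suprathreshold sample; amplitude is the
#' gaze change from the sample before onset to the last sample of the run.
#'
#' @param labels Per-sample labels from [classify_gaze_samples()].
#' @param gaze Unwrapped gaze series, degrees.
#' @param gaze_velocity Gaze velocity, deg/s.
#' @param rate Sampling rate, Hz.
#' @param merge_gap_samples Merge saccadic runs separated by gaps up to
#'   this many samples.
#' @return Tibble of class `saccade_set`: `onset_frame`, `offset_frame`,
#'   `onset` (s), `amplitude` (degrees), `peak_velocity` (deg/s),
#'   `direction` (+1/-1).
#' @export
detect_saccades <- function(labels, gaze, gaze_velocity, rate,
                            merge_gap_samples = 1) {
  sac <- !is.na(labels) & labels == "saccadic"
  runs <- true_runs(sac)
  if (nrow(runs) > 1 && merge_gap_samples > 0) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, 1] - last[2] - 1 <= merge_gap_samples) {
        merged[[length(merged)]] <- c(last[1], runs[i, 2])
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  n <- nrow(runs)
  amp <- peak <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- runs[i, 1]
    i1 <- runs[i, 2]
    pre <- max(1L, i0 - 1L)
    amp[i] <- gaze[i1] - gaze[pre]
    peak[i] <- max(abs(gaze_velocity[i0:i1]), na.rm = TRUE)
  }
  out <- tibble::tibble(
    onset_frame = as.integer(runs[, 1]),
    offset_frame = as.integer(runs[, 2]),
    onset = (runs[, 1] - 1) / rate,
    amplitude = amp,
    peak_velocity = peak,
    direction = sign(amp)
  )
  class(out) <- c("saccade_set", class(tibble::tibble()))
  attr(out, "rate") <- rate
  out
}

#' Per-fixation RMS stabilization
#'
#' For each fixation, the root-mean-square deviation of a series about its
#' within-fixation mean. Comparing this for head yaw and for gaze
#' quantifies how much the eyes stabilize gaze while the head moves.
#'
#' @param x Series in degrees (head yaw or gaze, unwrapped).
#' @param fixations A `fixation_set`.
#' @return List of class `rms_stabilization` with `per_fixation` (tibble:
#'   `start`, `duration_ms`, `rms`) and `median` (degrees).
#' @export
rms_stabilization <- function(x, fixations) {
  if (nrow(fixations) == 0) stop("empty fixation set", call. = FALSE)
  rms <- vapply(seq_len(nrow(fixations)), function(i) {
    v <- x[fixations$start_frame[i]:fixations$end_frame[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  structure(list(
    per_fixation = tibble::tibble(start = fixations$start,
                                  duration_ms = fixations$duration_ms,
                                  rms = rms),
    median = stats::median(rms, na.rm = TRUE)
  ), class = "rms_stabilization")
}

#' @export
print.rms_stabilization <- function(x, ...) {
  cat(sprintf("<rms_stabilization> %d fixations, median RMS %.3f deg\n",
              nrow(x$per_fixation), x$median))
  invisible(x)
}

#' Add gaze channels to a kinematic table
#'
#' Convenience pipeline verb: given a table with per-eye horizontal angles
#' and head yaw, adds vergence, mean eye position, unwrapped gaze, gaze
#' velocity and the compensatory/saccadic label.
#'
#' @param kin Tibble with columns named by `eye_r`, `eye_l`, `yaw`.
#' @param rate Sampling rate, Hz.
#' @param threshold Gaze-velocity threshold, deg/s.
#' @param eye_r,eye_l,yaw Column names.
#' @return `kin` with columns `vergence`, `mean_eye`, `gaze`,
#'   `gaze_velocity`, `gaze_label` appended.
#' @export
add_gaze_channels <- function(kin, rate, threshold = 180,
                              eye_r = "theta_r", eye_l = "theta_l",
                              yaw = "yaw") {
  E <- compute_mean_eye(kin[[eye_r]], kin[[eye_l]])
  G <- compute_gaze(kin[[yaw]], E)
  gv <- compute_velocity(G, rate)
  dplyr::mutate(kin,
                vergence = compute_vergence(kin[[eye_r]], kin[[eye_l]]),
                mean_eye = E,
                gaze = G,
                gaze_velocity = gv,
                gaze_label = classify_gaze_samples(gv, threshold))
}

#' Write saccade or fixation tables to CSV
#'
#' @param x A `saccade_set` or `fixation_set`.
#' @param path Output path.
#' @export
write_events_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
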