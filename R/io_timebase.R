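#' Read a markerless-tracker landmark CSV
#'
#' Parses the three-header-row dialect emitted by common markerless pose
#' trackers: a scorer row, a bodyparts row, and a coords row
#' (`x`/`y`/`likelihood` triplets), followed by one row per video frame with
#' a leading frame index. Missing cells are kept as invalid points with
#' confidence 0 so downstream stages can mask them.
#'
#' @param path Path to the CSV file.
#' @param frame_rate Acquisition frame rate in Hz used to assign timestamps
#'   (`t = frame / frame_rate`, first frame at t = 0).
#' @return A tibble in long format with one row per frame and point:
#'   columns `frame` (0-based), `t` (seconds), `point`, `x`, `y`,
#'   `likelihood`. The frame rate is stored in attribute `frame_rate`.
#' @export
read_tracker_landmarks <- function(path, frame_rate = 60) {
  stopifnot(file.exists(path), frame_rate > 0)
  lines <- readr::read_lines(path, n_max = 3)
  if (length(lines) < 3) {
    stop("malformed landmark file: fewer than three header rows", call. = FALSE)
  }
  hdr <- lapply(lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  ncols <- vapply(hdr, length, integer(1))
  if (length(unique(ncols)) != 1) {
    stop("malformed landmark file: header rows disagree in column count",
         call. = FALSE)
  }
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if ((ncols[1] - 1) %% 3 != 0 ||
      !all(coords == rep(c("x", "y", "likelihood"), length.out = length(coords)))) {
    stop("malformed landmark file: expected x, y, likelihood triplets",
         call. = FALSE)
  }
  points <- bodyparts[seq(1, length(bodyparts), by = 3)]
  if (anyDuplicated(points)) {
    stop("malformed landmark file: duplicated point names", call. = FALSE)
  }
  dat <- utils::read.csv(path, skip = 3, header = FALSE,
                         col.names = c("frame", paste0("V", seq_along(coords))),
                         colClasses = "numeric")
  n <- nrow(dat)
  out <- tibble::tibble(
    frame = rep(dat$frame, times = length(points)),
    point = rep(points, each = n),
    x = as.vector(as.matrix(dat[, 1 + seq(1, length(coords), by = 3), drop = FALSE])),
    y = as.vector(as.matrix(dat[, 1 + seq(2, length(coords), by = 3), drop = FALSE])),
    likelihood = as.vector(as.matrix(dat[, 1 + seq(3, length(coords), by = 3),
                                         drop = FALSE]))
  )
  # missing coordinates -> invalid point, confidence 0
  bad <- is.na(out$x) | is.na(out$y) | is.na(out$likelihood)
  out$likelihood[bad] <- 0
  out <- dplyr::arrange(out, .data$frame, .data$point)
  out <- dplyr::mutate(out, t = .data$frame / frame_rate, .after = "frame")
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Read an inertial-measurement CSV and convert voltages to physical units
#'
#' Expects columns `t, ax, ay, az, gx, gy, gz`: time in seconds, three
#' accelerometer channels and three gyroscope channels in volts.
#' Accelerometer voltages are converted to m/s^2 and gyroscope voltages to
#' rad/s by the supplied linear gains; the gyroscope is deliberately left
#' unfiltered (transient removal on the accelerometer happens later, in
#' [process_imu()]).
#'
#' @param path Path to the CSV file.
#' @param accel_gain (m/s^2) per volt; scalar or length-3 (one per channel).
#' @param gyro_gain (rad/s) per volt; scalar or length-3.
#' @return Tibble with columns `t`, `ax`, `ay`, `az` (m/s^2), `gx`, `gy`,
#'   `gz` (rad/s) and attribute `sample_rate` (Hz, estimated from `t`).
#' @export
read_imu_csv <- function(path, accel_gain = 1, gyro_gain = 1) {
  stopifnot(file.exists(path))
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(dat))) {
    stop("IMU file missing channel(s): ",
         paste(setdiff(need, names(dat)), collapse = ", "), call. = FALSE)
  }
  accel_gain <- rep_len(accel_gain, 3)
  gyro_gain <- rep_len(gyro_gain, 3)
  out <- tibble::tibble(
    t = dat$t,
    ax = dat$ax * accel_gain[1], ay = dat$ay * accel_gain[2],
    az = dat$az * accel_gain[3],
    gx = dat$gx * gyro_gain[1], gy = dat$gy * gyro_gain[2],
    gz = dat$gz * gyro_gain[3]
  )
  if (is.unsorted(out$t, strictly = TRUE)) {
    stop("IMU timestamps must be strictly increasing", call. = FALSE)
  }
  attr(out, "sample_rate") <- 1 / stats::median(diff(out$t))
  out
}

# window in ms -> odd sample count at `rate`: nearest odd integer >= 1
window_samples <- function(window_ms, rate) {
  m <- window_ms * rate / 1000
  max(1L, 2L * as.integer(floor(m / 2)) + 1L)
}

#' Sliding median filter with shrinking end windows
#'
#' Applies a centered running median over a window given in milliseconds,
#' converted to the nearest odd sample count at the series' rate (500 ms at
#' 60 Hz gives 31 samples; 266.7 ms at 50 Hz gives 13). At the series ends,
#' where a full centered window does not fit, the window is clipped to the
#' available samples. NA (masked) samples are ignored within
#' each window; an all-NA window yields NA.
#'
#' @param x Numeric series.
#' @param window_ms Window length in milliseconds (> 0).
#' @param rate Sampling rate of `x` in Hz.
#' @return Filtered series, same length as `x`.
#' @export
median_filter <- function(x, window_ms, rate) {
  stopifnot(window_ms > 0, rate > 0)
  k <- window_samples(window_ms, rate)
  if (k == 1L || window_ms < 1000 / rate) {
    if (window_ms < 1000 / rate) {
      warning("median_filter window shorter than one sample; returning input")
    }
    return(x)
  }
  n <- length(x)
  if (n == 0) return(x)
  h <- (k - 1L) %/% 2L
  clipped_median <- function(idx) {
    vapply(idx, function(i) {
      w <- x[max(1L, i - h):min(n, i + h)]
      if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
    }, numeric(1))
  }
  if (!anyNA(x) && n >= k) {
    # fast interior via runmed; clipped windows only at the ends
    out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
    edge <- c(seq_len(h), seq(n - h + 1L, n))
    out[edge] <- clipped_median(edge)
    return(out)
  }
  clipped_median(seq_len(n))
}

#' Linear resampling onto a target grid without extrapolation
#'
#' Linearly interpolates a timestamped series at the requested output times.
#' Output times outside the source range are flagged invalid (NA) rather
#' than extrapolated. Angle-valued series are unwrapped before
#' interpolation and re-wrapped after, so a yaw trace crossing the
#' -180/+180 seam never produces a spurious 360 degree jump.
#'
#' @param t Source timestamps, strictly increasing, length >= 2.
#' @param x Source values, same length as `t`.
#' @param t_out Output timestamps.
#' @param angle Logical; treat `x` as a wrapped angle in degrees.
#' @return Numeric vector of length `length(t_out)`.
#' @export
resample_series <- function(t, x, t_out, angle = FALSE) {
  stopifnot(length(t) == length(x), length(t) >= 2)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (angle) x <- unwrap_angle(x)
  out <- stats::approx(t, x, xout = t_out, method = "linear", rule = 1,
                       ties = "ordered")$y
  if (angle) out <- wrap_angle(out)
  out
}

# uniform grid at `rate` covering the overlap [t0, t1], aligned to k/rate
target_grid <- function(t0, t1, rate) {
  i0 <- ceiling(t0 * rate - 1e-9)
  i1 <- floor(t1 * rate + 1e-9)
  if (i1 < i0) stop("empty overlap of time ranges", call. = FALSE)
  seq(i0, i1) / rate
}

#' Place several timestamped streams on one shared uniform timebase
#'
#' All channels are linearly interpolated to a single grid at `target_rate`
#' (default 60 Hz) spanning the overlap of every input's time range, so that
#' channels acquired by different devices (cameras at different rates, a
#' 50 Hz inertial unit) can be analysed sample-by-sample. Channels named in
#' `angle_channels` are interpolated on the unwrapped line and re-expressed
#' in (-180, 180].
#'
#' @param streams Named list; each element a data frame with a `t` column
#'   (seconds) plus one or more numeric value columns. Value-column names
#'   must be unique across streams.
#' @param target_rate Output rate in Hz.
#' @param angle_channels Character vector of value-column names to treat as
#'   wrapped angles (degrees).
#' @return Tibble with column `t` (the shared grid) followed by every value
#'   column, resampled. Samples outside a source's own range are NA.
#' @export
build_channelset <- function(streams, target_rate = 60, angle_channels = character()) {
  stopifnot(is.list(streams), length(streams) >= 1, target_rate > 0)
  ranges <- vapply(streams, function(s) range(s$t), numeric(2))
  grid <- target_grid(max(ranges[1, ]), min(ranges[2, ]), target_rate)
  out <- tibble::tibble(t = grid)
  for (s in streams) {
    for (col in setdiff(names(s), "t")) {
      if (col %in% names(out)) {
        stop("duplicate channel name across streams: ", col, call. = FALSE)
      }
      out[[col]] <- resample_series(s$t, s[[col]], grid,
                                    angle = col %in% angle_channels)
    }
  }
  attr(out, "rate") <- target_rate
  out
}

#' Read a plain-text configuration file
#'
#' Accepts either simple `key = value` lines (comments with `#`) or YAML if
#' the yaml package is installed. Values that parse as numbers become
#' numeric.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    return(yaml::read_yaml(path))
  }
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[1]), character(1)))
}
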