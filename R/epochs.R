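new_epoch_set <- function(label, start, end, rate) {
  out <- tibble::tibble(label = label, start = start, end = end)
  out <- dplyr::arrange(out, .data$label, .data$start)
  attr(out, "rate") <- rate
  class(out) <- c("epoch_set", class(tibble::tibble()))
  out
}

# turn a per-sample logical mask into [start, end) intervals in seconds
mask_to_intervals <- function(mask, t, rate) {
  runs <- true_runs(mask)
  if (nrow(runs) == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  tibble::tibble(start = t[runs[, 1]], end = t[runs[, 2]] + 1 / rate)
}

merge_and_filter_intervals <- function(iv, merge_gap_s = 0, min_duration_s = 0) {
  if (nrow(iv) == 0) return(iv)
  iv <- dplyr::arrange(iv, .data$start)
  start <- iv$start
  end <- iv$end
  ks <- start[1]; ke <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_len(nrow(iv))[-1]) {
    if (start[i] - ke <= merge_gap_s + 1e-12) {
      ke <- max(ke, end[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      ks <- start[i]; ke <- end[i]
    }
  }
  out_s <- c(out_s, ks); out_e <- c(out_e, ke)
  keep <- (out_e - out_s) >= min_duration_s - 1e-12
  tibble::tibble(start = out_s[keep], end = out_e[keep])
}

#' Label moving vs stationary samples
#'
#' Samples with median-filtered speed strictly greater than the threshold
#' (1 cm/s by default) are moving; valid samples at or below it are
#' stationary. Contiguous runs become half-open intervals.
#'
#' @param speed Speed series (cm/s), already median filtered (see
#'   [compute_speed()]).
#' @param rate Sampling rate, Hz.
#' @param threshold Speed threshold, cm/s.
#' @param t Optional timestamps; defaults to `(0:(n-1))/rate`.
#' @return An `epoch_set` tibble with labels `moving` and `stationary`,
#'   columns `label`, `start`, `end` (seconds, `[start, end)`).
#' @export
detect_moving <- function(speed, rate, threshold = 1, t = NULL) {
  n <- length(speed)
  if (is.null(t)) t <- (seq_len(n) - 1) / rate
  moving <- !is.na(speed) & speed > threshold
  stationary <- !is.na(speed) & !moving
  mv <- mask_to_intervals(moving, t, rate)
  st <- mask_to_intervals(stationary, t, rate)
  new_epoch_set(c(rep("moving", nrow(mv)), rep("stationary", nrow(st))),
                c(mv$start, st$start), c(mv$end, st$end), rate)
}

#' Detect prey-approach epochs
#'
#' An approach sample satisfies all three criteria simultaneously: speed
#' greater than 1 cm/s, cricket azimuth strictly between -45 and 45
#' degrees, and distance to the cricket decreasing faster than 10 cm/s
#' (range rate below -10 cm/s). Boundary values are excluded (strict
#' inequalities). Contiguous qualifying runs become intervals; optionally,
#' gaps up to `merge_gap_ms` are bridged and intervals shorter than
#' `min_duration_ms` dropped (set both to 0 for the raw per-sample
#' conjunction). Non-approach intervals are the complement within valid
#' samples.
#'
#' @param speed Median-filtered speed, cm/s.
#' @param azimuth Cricket azimuth, degrees.
#' @param range_rate Smoothed range rate, cm/s (negative while closing).
#' @param rate Sampling rate, Hz.
#' @param speed_threshold,azimuth_limit,closing_threshold The three
#'   criteria (cm/s, degrees, cm/s).
#' @param merge_gap_ms Bridge sub-threshold gaps up to this long (ms).
#' @param min_duration_ms Drop approach intervals shorter than this (ms).
#' @param t Optional timestamps.
#' @return `epoch_set` with labels `approach` and `non_approach`.
#' @export
detect_approaches <- function(speed, azimuth, range_rate, rate,
                              speed_threshold = 1, azimuth_limit = 45,
                              closing_threshold = 10,
                              merge_gap_ms = 100, min_duration_ms = 250,
                              t = NULL) {
  n <- length(speed)
  stopifnot(length(azimuth) == n, length(range_rate) == n)
  if (is.null(t)) t <- (seq_len(n) - 1) / rate
  valid <- !is.na(speed) & !is.na(azimuth) & !is.na(range_rate)
  appr <- valid & speed > speed_threshold & abs(azimuth) < azimuth_limit &
    range_rate < -closing_threshold
  iv <- mask_to_intervals(appr, t, rate)
  iv <- merge_and_filter_intervals(iv, merge_gap_ms / 1000, min_duration_ms / 1000)
  # complement within valid samples
  in_appr <- interval_mask(iv, t)
  non <- mask_to_intervals(valid & !in_appr, t, rate)
  new_epoch_set(c(rep("approach", nrow(iv)), rep("non_approach", nrow(non))),
                c(iv$start, non$start), c(iv$end, non$end), rate)
}

interval_mask <- function(iv, timestamps) {
  mask <- rep(FALSE, length(timestamps))
  for (i in seq_len(nrow(iv))) {
    mask <- mask | (timestamps >= iv$start[i] - 1e-12 &
                      timestamps < iv$end[i] - 1e-12)
  }
  mask
}

#' Per-sample mask for an epoch set
#'
#' Half-open convention: a timestamp equal to an interval's end is outside.
#'
#' @param epochs An `epoch_set`.
#' @param timestamps Sample times, seconds.
#' @param label Restrict to one label (default: all intervals).
#' @return Logical vector.
#' @export
epoch_mask <- function(epochs, timestamps, label = NULL) {
  iv <- epochs
  if (!is.null(label)) iv <- iv[iv$label %in% label, , drop = FALSE]
  interval_mask(iv, timestamps)
}

#' Write epochs to disk
#'
#' `bed` writes a BED-like 3-column text table (label, start_s, end_s,
#' tab-separated, no header); `json` writes the same records as JSON.
#'
#' @param epochs An `epoch_set`.
#' @param path Output path.
#' @param format `"bed"` or `"json"`.
#' @export
write_epochs <- function(epochs, path, format = c("bed", "json")) {
  format <- match.arg(format)
  if (format == "bed") {
    readr::write_tsv(tibble::as_tibble(epochs)[, c("label", "start", "end")],
                     path, col_names = FALSE)
  } else {
    jsonlite::write_json(tibble::as_tibble(epochs), path, digits = NA)
  }
  invisible(path)
}
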