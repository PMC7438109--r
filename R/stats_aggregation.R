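#' Lagged cross-correlation between two synchronized series
#'
#' Pearson correlation at every integer-sample lag up to `max_lag_s`.
#' Positive lag means `b` follows `a` (a copy of `a` delayed by k samples
#' peaks at lag +k). When a mask is supplied (e.g. approach epochs), the
#' correlation is computed within each contiguous masked segment separately
#' and combined across segments by sample-weighted averaging, so that
#' behavioral regimes are never mixed across epoch boundaries. Optional
#' first-differencing of either or both series is applied per segment
#' before correlating.
#'
#' @param a,b Numeric series of equal length.
#' @param rate Sampling rate, Hz.
#' @param max_lag_s Maximum lag, seconds.
#' @param mode One of `"raw"`, `"diff_a"`, `"diff_b"`, `"diff_both"`.
#' @param mask Optional logical vector; only samples where TRUE are used.
#' @return Tibble of class `lag_correlation`: `lag` (s), `lag_samples`,
#'   `r`, `n` (pairs contributing).
#' @export
lagged_xcorr <- function(a, b, rate, max_lag_s = 2,
                         mode = c("raw", "diff_a", "diff_b", "diff_both"),
                         mask = NULL) {
  mode <- match.arg(mode)
  n <- length(a)
  stopifnot(length(b) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- mask & !is.na(a) & !is.na(b)
  L <- as.integer(round(max_lag_s * rate))
  segs <- true_runs(mask)
  if (nrow(segs) == 0) stop("mask selects no valid samples", call. = FALSE)
  lags <- seq(-L, L)
  r_acc <- numeric(length(lags))
  n_acc <- numeric(length(lags))
  for (s in seq_len(nrow(segs))) {
    sa <- a[segs[s, 1]:segs[s, 2]]
    sb <- b[segs[s, 1]:segs[s, 2]]
    if (mode %in% c("diff_a", "diff_both")) sa <- diff(sa)
    if (mode %in% c("diff_b", "diff_both")) sb <- diff(sb)
    if (mode %in% c("diff_a", "diff_b")) {
      m <- min(length(sa), length(sb))
      sa <- sa[seq_len(m)]
      sb <- sb[seq_len(m)]
    }
    m <- length(sa)
    for (j in seq_along(lags)) {
      k <- lags[j]
      # pair (a[i], b[i+k])
      i0 <- max(1, 1 - k)
      i1 <- min(m, m - k)
      if (i1 - i0 + 1 < 2) next
      x <- sa[i0:i1]
      y <- sb[(i0 + k):(i1 + k)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r_acc[j] <- r_acc[j] + stats::cor(x, y) * (i1 - i0 + 1)
      n_acc[j] <- n_acc[j] + (i1 - i0 + 1)
    }
  }
  if (all(n_acc == 0)) stop("no segment long enough for any lag", call. = FALSE)
  out <- tibble::tibble(lag = lags / rate, lag_samples = lags,
                        r = ifelse(n_acc > 0, r_acc / n_acc, NA_real_),
                        n = n_acc)
  class(out) <- c("lag_correlation", class(tibble::tibble()))
  out
}

#' Event-triggered average of a series
#'
#' Extracts a window around each event time, optionally transforms the
#' traces (e.g. absolute value for azimuth-relative-to-target analyses),
#' and averages across events at each offset.
#'
#' @param x Series.
#' @param rate Sampling rate, Hz.
#' @param events Event times in seconds (aligned to the series' own
#'   timebase, first sample at t = 0).
#' @param window `c(pre, post)` in seconds (both positive); offsets span
#'   `-pre..post` and include 0 (event onset).
#' @param transform `"identity"` or `"abs"`, applied before averaging.
#' @param partial `"drop"` (default) discards events whose window leaves
#'   the series; `"pad"` keeps them with NA outside.
#' @return Tibble of class `triggered_average`: `offset` (s), `mean`,
#'   `sem`, `n`.
#' @export
triggered_average <- function(x, rate, events, window = c(0.5, 0.5),
                              transform = c("identity", "abs"),
                              partial = c("drop", "pad")) {
  transform <- match.arg(transform)
  partial <- match.arg(partial)
  if (length(events) == 0) stop("no events", call. = FALSE)
  n <- length(x)
  pre <- as.integer(round(window[1] * rate))
  post <- as.integer(round(window[2] * rate))
  offs <- seq(-pre, post)
  idx0 <- as.integer(round(events * rate)) + 1L
  rows <- lapply(idx0, function(i) {
    ii <- i + offs
    if (partial == "drop" && (ii[1] < 1 || ii[length(ii)] > n)) return(NULL)
    v <- rep(NA_real_, length(offs))
    ok <- ii >= 1 & ii <= n
    v[ok] <- x[ii[ok]]
    v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no events with a full window inside the data", call. = FALSE)
  M <- do.call(rbind, rows)
  if (transform == "abs") M <- abs(M)
  nn <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  sem <- apply(M, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) return(NA_real_)
    stats::sd(col) / sqrt(length(col))
  })
  out <- tibble::tibble(offset = offs / rate, mean = mu, sem = sem, n = nn)
  attr(out, "n_events") <- nrow(M)
  class(out) <- c("triggered_average", class(tibble::tibble()))
  out
}

#' Head and gaze targeting accuracy before and after saccades
#'
#' Samples the absolute head and gaze azimuth (angle to the target) a fixed
#' offset before and after each saccade onset, returning the four
#' distributions and their medians. Used to ask whether saccades target the
#' prey better than the head does.
#'
#' @param abs_az_head,abs_az_gaze Absolute azimuth of head and gaze to the
#'   target (degrees), synchronized series.
#' @param onsets Saccade onset times, seconds.
#' @param rate Sampling rate, Hz.
#' @param pre_s,post_s Sampling offsets before/after onset (seconds).
#' @return List of class `pre_post_saccade`: `samples` (long tibble:
#'   `saccade`, `phase`, `channel`, `value`) and `summary` (tibble:
#'   `phase`, `channel`, `median`, `sem`, `n`). `sem` is the standard
#'   error of the mean of the distribution.
#' @export
pre_post_saccade_stats <- function(abs_az_head, abs_az_gaze, onsets, rate,
                                   pre_s = 0.25, post_s = 0.25) {
  if (length(onsets) == 0) stop("no saccades in mask", call. = FALSE)
  n <- length(abs_az_head)
  stopifnot(length(abs_az_gaze) == n)
  idx <- as.integer(round(onsets * rate)) + 1L
  grab <- function(series, shift) {
    ii <- idx + shift
    out <- rep(NA_real_, length(ii))
    ok <- ii >= 1 & ii <= n
    out[ok] <- series[ii[ok]]
    out
  }
  dpre <- as.integer(round(pre_s * rate))
  dpost <- as.integer(round(post_s * rate))
  samples <- dplyr::bind_rows(
    tibble::tibble(saccade = seq_along(idx), phase = "pre", channel = "head",
                   value = grab(abs_az_head, -dpre)),
    tibble::tibble(saccade = seq_along(idx), phase = "pre", channel = "gaze",
                   value = grab(abs_az_gaze, -dpre)),
    tibble::tibble(saccade = seq_along(idx), phase = "post", channel = "head",
                   value = grab(abs_az_head, dpost)),
    tibble::tibble(saccade = seq_along(idx), phase = "post", channel = "gaze",
                   value = grab(abs_az_gaze, dpost))
  )
  samples <- samples[!is.na(samples$value), ]
  if (nrow(samples) == 0) stop("no usable saccade-aligned samples", call. = FALSE)
  summary <- samples |>
    dplyr::group_by(.data$phase, .data$channel) |>
    dplyr::summarise(median = stats::median(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(samples = samples, summary = summary),
            class = "pre_post_saccade")
}

#' @export
print.pre_post_saccade <- function(x, ...) {
  cat("<pre_post_saccade> medians of |azimuth| (deg):\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Ordinary least-squares fit of vergence against head pitch
#'
#' Vergence covaries with head pitch (as the head tilts down the eyes
#' diverge to keep the visual scene vertically stable); this fits the line
#' `V = slope * P + intercept` and reports the Pearson correlation.
#'
#' @param pitch Head pitch, degrees (positive nose-up).
#' @param vergence Vergence, degrees.
#' @param mask Optional logical vector selecting samples.
#' @return Object of class `pitch_vergence_fit`: list with `slope`,
#'   `intercept`, `r`, `n`, and the underlying `lm` fit as `$fit`.
#' @export
pitch_vergence_fit <- function(pitch, vergence, mask = NULL) {
  n <- length(pitch)
  stopifnot(length(vergence) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  ok <- mask & !is.na(pitch) & !is.na(vergence)
  if (sum(ok) < 3) stop("need at least 3 unmasked samples", call. = FALSE)
  P <- pitch[ok]
  V <- vergence[ok]
  if (stats::sd(P) == 0) stop("pitch has zero variance", call. = FALSE)
  fit <- stats::lm(V ~ P)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(P, V), n = sum(ok), fit = fit),
            class = "pitch_vergence_fit")
}

#' @export
print.pitch_vergence_fit <- function(x, ...) {
  cat(sprintf(
    "<pitch_vergence_fit> V = %.3f * P + %.3f (r = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Conditional distribution of a series under a mask
#'
#' Restricts a series to samples satisfying a condition (for instance, eye
#' velocity while head yaw is nearly constant) and returns a histogram and
#' the median.
#'
#' @param x Series.
#' @param mask Logical vector.
#' @param binwidth Histogram bin width, in the units of `x`.
#' @return List of class `masked_distribution`: `bins` (tibble: `mid`,
#'   `count`), `median`, `n`, `values`.
#' @export
masked_distribution <- function(x, mask, binwidth = 5) {
  stopifnot(length(mask) == length(x))
  v <- x[mask & !is.na(x)]
  if (length(v) == 0) stop("mask selects no valid samples", call. = FALSE)
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(bins = tibble::tibble(mid = h$mids, count = h$counts),
                 median = stats::median(v), n = length(v), values = v),
            class = "masked_distribution")
}

#' @export
print.masked_distribution <- function(x, ...) {
  cat(sprintf("<masked_distribution> n = %d, median = %.3f\n", x$n, x$median))
  invisible(x)
}
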