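#' Wrap angles to (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector with every element mapped into (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -180, 360, 45))
wrap_angle <- function(x) {
  out <- x - 360 * floor(x / 360 + 0.5)
  # floor-based wrap yields [-180, 180); move -180 to +180
  out[!is.na(out) & out <= -180] <- out[!is.na(out) & out <= -180] + 360
  out
}

#' Unwrap a wrapped angle series
#'
#' Reconstructs a continuous angle trace from one wrapped to (-180, 180] by
#' assuming successive samples never jump by more than 180 degrees. NA runs
#' are bridged so the segments on either side stay consistent.
#'
#' @param x Numeric vector of angles in degrees, possibly wrapped.
#' @return Numeric vector on the unwrapped line; starts at `x[1]`.
#' @export
unwrap_angle <- function(x) {
  n <- length(x)
  if (n < 2) return(x)
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- which(ok)
  v <- x[idx]
  steps <- wrap_angle(diff(v))
  out <- rep(NA_real_, n)
  out[idx] <- v[1] + c(0, cumsum(steps))
  out
}

# degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# contiguous runs of TRUE in a logical vector (NA treated as FALSE);
# returns a two-column matrix of first/last indices
true_runs <- function(mask) {
  mask <- !is.na(mask) & mask
  if (!any(mask)) return(matrix(integer(0), ncol = 2))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}
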