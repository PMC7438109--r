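#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an eye-camera calibration
#'
#' @param x An `eye_calibration` object.
#' @param ... Unused.
#' @return One-row tibble with `cx`, `cy`, `R`, `n_frames_used`,
#'   `residual`.
#' @method tidy eye_calibration
#' @export
tidy.eye_calibration <- function(x, ...) {
  tibble::tibble(cx = x$cx, cy = x$cy, R = x$R,
                 n_frames_used = x$n_frames_used, residual = x$residual)
}

#' @rdname tidy.eye_calibration
#' @method glance eye_calibration
#' @export
glance.eye_calibration <- function(x, ...) {
  tibble::tibble(n_frames_used = x$n_frames_used, residual = x$residual,
                 min_eccentricity = x$min_eccentricity)
}

#' Tidy a pitch-vergence regression
#'
#' @param x A `pitch_vergence_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`), plus
#'   `r` for the slope row via [glance.pitch_vergence_fit()].
#' @method tidy pitch_vergence_fit
#' @export
tidy.pitch_vergence_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.pitch_vergence_fit
#' @method glance pitch_vergence_fit
#' @export
glance.pitch_vergence_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r_squared = x$r^2, n = x$n)
}
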