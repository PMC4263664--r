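# Contour smoothing: an ideal low-pass filter on the periodic sequence of
# center distances (rho' = IFFT(H . FFT(rho))) for near-circular contours,
# and a closed least-squares piecewise-cubic (Bezier) fit for polygonal
# contours.

#' Smoothing parameters
#'
#' @param keep_harmonics number of Fourier harmonics passed by the ideal
#'   low-pass filter (two-sided; the DC term is always kept).
#' @param bezier_segments number of cubic segments of the closed fit.
#' @param bezier_samples number of output samples (>= 16).
#' @return list of class `smoothing_params`.
#' @export
smoothing_params <- function(keep_harmonics = 8, bezier_segments = 12,
                             bezier_samples = 120) {
  stopifnot(keep_harmonics >= 1, bezier_samples >= 16, bezier_segments >= 4)
  structure(list(keep_harmonics = as.integer(keep_harmonics),
                 bezier_segments = as.integer(bezier_segments),
                 bezier_samples = as.integer(bezier_samples)),
            class = "smoothing_params")
}

#' Ideal low-pass smoothing of a periodic radius sequence
#'
#' Discrete Fourier transform of the radii; all coefficients with harmonic
#' index above `keep_harmonics` are zeroed (two-sided); inverse transform.
#' The DC coefficient is untouched, so the mean radius is preserved
#' exactly.
#'
#' @param radii positive numeric sequence (length >= 4) of center distances
#'   at uniformly spaced angles.
#' @param params an [smoothing_params()] (or a number of harmonics).
#' @return numeric sequence of the same length.
#' @export
fft_smooth <- function(radii, params = smoothing_params()) {
  if (is.numeric(params)) params <- smoothing_params(keep_harmonics = params)
  n <- length(radii)
  if (n < 4) stop("need at least 4 radii")
  if (any(!is.finite(radii)) || any(radii <= 0)) stop("radii must be positive and finite")
  co <- stats::fft(radii)
  k <- pmin(0:(n - 1), n - (0:(n - 1)))  # two-sided harmonic index
  co[k > params$keep_harmonics] <- 0
  out <- stats::fft(co, inverse = TRUE) / n
  if (max(abs(Im(out))) > 1e-6) stop("unexpected imaginary residue in FFT smoothing")
  out <- Re(out)
  if (any(out <= 0)) stop("over-aggressive cutoff: smoothed radius is non-positive")
  out
}

# Periodic uniform cubic B-spline basis weights at local parameter u in [0,1).
bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# Design matrix of a closed uniform cubic spline with S control points,
# evaluated at parameters t in [0, S).
bspline_design <- function(t, S) {
  seg <- floor(t) %% S
  u <- t - floor(t)
  W <- bspline_weights(u)
  A <- matrix(0, length(t), S)
  for (k in 0:3) {
    idx <- ((seg - 1 + k) %% S) + 1
    A[cbind(seq_along(t), idx)] <- A[cbind(seq_along(t), idx)] + W[, k + 1]
  }
  A
}

#' Closed piecewise-cubic (Bezier) contour smoothing
#'
#' Fits a closed piecewise-cubic curve with smoothly joined segments to the
#' contour vertices by least squares (control points of a periodic uniform
#' cubic spline; every span is an exact cubic Bezier arc and the joins are
#' C2), then resamples it uniformly.
#'
#' @param ct an [contour()] with at least 4 vertices.
#' @param params an [smoothing_params()].
#' @return An [contour()] with `bezier_samples` vertices.
#' @export
bezier_smooth <- function(ct, params = smoothing_params()) {
  if (!is_contour(ct)) ct <- contour(ct)
  n <- nrow(ct)
  if (n < 4) stop("Bezier smoothing needs at least 4 points")
  S <- max(4L, min(params$bezier_segments, n))
  t_in <- (seq_len(n) - 1) / n * S
  A <- bspline_design(t_in, S)
  ctrl <- tryCatch(qr.solve(A, cbind(ct$x, ct$y)),
                   error = function(e) stop("degenerate contour: smoothing fit is singular"))
  t_out <- (seq_len(params$bezier_samples) - 1) / params$bezier_samples * S
  out <- bspline_design(t_out, S) %*% ctrl
  contour(out[, 1], out[, 2])
}
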