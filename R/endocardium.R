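# Endocardial contour extraction. Two branches: the plain convex hull of the
# refined blood pool, and an outflow-tract (LVOT) branch that prunes the
# leak of bright cavity signal through the missing basal wall using context
# from the previously segmented slice.

#' Major axis of the moment-equivalent ellipse
#'
#' Length of the major axis of the ellipse with the same normalised second
#' central moments as the mask (the regionprops convention: four times the
#' square root of the largest covariance eigenvalue).
#'
#' @param mask non-empty logical matrix.
#' @return length in pixels.
#' @export
major_axis_length <- function(mask) {
  pts <- mask_points(mask)
  if (!nrow(pts)) stop("mask is empty")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  dx <- pts[, 1] - mx; dy <- pts[, 2] - my
  cxx <- mean(dx^2); cyy <- mean(dy^2); cxy <- mean(dx * dy)
  lam_max <- (cxx + cyy) / 2 + sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  4 * sqrt(lam_max)
}

#' LVOT decision from the basal-ward major-axis jump
#'
#' Marching from the mid slice toward the base, a basal slice with the left
#' ventricular outflow tract is flagged when the major axis of the current
#' blood pool's convex hull exceeds the previous slice's by more than
#' `threshold` (strict inequality; default ratio threshold 1.2).
#'
#' @param L_current,L_previous major-axis lengths in pixels, both positive.
#' @param threshold dimensionless ratio threshold.
#' @return list of class `lv_lvot`: `major_axis_current`,
#'   `major_axis_previous`, `ratio`, `threshold`, `has_lvot`.
#' @export
detect_lvot <- function(L_current, L_previous, threshold = 1.2) {
  if (!is.finite(L_current) || !is.finite(L_previous) ||
      L_current <= 0 || L_previous <= 0)
    stop("major-axis lengths must be positive")
  ratio <- L_current / L_previous
  structure(list(major_axis_current = L_current, major_axis_previous = L_previous,
                 ratio = ratio, threshold = threshold,
                 has_lvot = ratio > threshold),
            class = "lv_lvot")
}

#' Endocardial contour without LVOT
#'
#' Convex hull of the blood pool's boundary pixels, ordered
#' counter-clockwise in image coordinates.
#'
#' @param pool non-empty logical blood-pool mask (ROI frame).
#' @return An [contour()] in the same frame.
#' @export
endo_without_lvot <- function(pool) {
  if (!any(pool)) stop("blood pool is empty")
  pts <- mask_points(mask_boundary(pool))
  if (nrow(pts) < 3L) stop("degenerate blood pool: fewer than 3 boundary pixels")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) stop("degenerate (collinear) blood pool")
  ct <- contour(pts[h, 1], pts[h, 2])
  if (contour_area(ct) < 1e-9) stop("degenerate (collinear) blood pool")
  ct
}

#' Algebraic least-squares circle fit
#'
#' Kasa-style fit: solve `2ax + 2by + c = x^2 + y^2` in least squares;
#' center `(a, b)`, radius `sqrt(c + a^2 + b^2)`. Closed-form and
#' deterministic.
#'
#' @param points matrix or data frame with columns `x`, `y` (>= 3
#'   non-collinear points).
#' @param outlier_threshold stored pruning threshold in pixels (used by
#'   [endo_with_lvot()]).
#' @return list of class `lv_circle`: `center` (x, y), `radius`,
#'   `outlier_threshold`.
#' @export
fit_circle <- function(points, outlier_threshold = 3) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) names(pts)[1:2] <- c("x", "y")
  if (nrow(pts) < 3L) stop("circle fit needs at least 3 points")
  A <- cbind(2 * pts$x, 2 * pts$y, 1)
  b <- pts$x^2 + pts$y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) stop("collinear points: circle fit is singular"))
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 1e-12) stop("collinear points: circle fit is singular")
  structure(list(center = c(x = unname(sol[1]), y = unname(sol[2])),
                 radius = sqrt(r2), outlier_threshold = outlier_threshold),
            class = "lv_circle")
}

#' Endocardial contour at an LVOT slice
#'
#' The thresholded binary ROI is masked with the dilated blood pool of the
#' previous slice; the masked region's boundary points are expressed in
#' polar form about the previous pool center; a least-squares circle is
#' fitted and points whose polar radius exceeds the fitted radius by more
#' than `outlier_px` (the outflow leak) are dropped; survivors are connected
#' in angular order, their convex hull taken, and the result smoothed with
#' a closed Bezier fit.
#'
#' @param binary_roi logical ROI matrix (thresholded at the chosen blood-pool
#'   threshold).
#' @param previous_pool logical ROI-frame mask of the previous slice's blood
#'   pool (already transported into the current ROI).
#' @param previous_center numeric `(x, y)` pole, ROI frame, 0-based.
#' @param dilation_px disc radius used to dilate `previous_pool`.
#' @param outlier_px radial pruning threshold in pixels.
#' @param smooth_params an [smoothing_params()] for the Bezier step.
#' @return An [contour()] in the ROI frame.
#' @export
endo_with_lvot <- function(binary_roi, previous_pool, previous_center,
                           dilation_px = 3, outlier_px = 3,
                           smooth_params = smoothing_params()) {
  if (!any(previous_pool)) stop("previous blood pool is empty")
  masked <- binary_roi & dilate_disc(previous_pool, dilation_px)
  if (!any(masked)) stop("no blood-pool pixels survive the previous-slice mask")
  pts <- mask_points(mask_boundary(masked))
  if (nrow(pts) < 3L) stop("fewer than 3 boundary points at the LVOT slice")
  dx <- pts[, 1] - previous_center[1]
  dy <- previous_center[2] - pts[, 2]
  r <- sqrt(dx^2 + dy^2)
  fit <- fit_circle(data.frame(x = pts[, 1], y = pts[, 2]), outlier_px)
  keep <- r <= fit$radius + outlier_px
  if (sum(keep) < 3L) stop("fewer than 3 points survive the circle-fit pruning")
  th <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  o <- order(th)
  survivors <- contour(pts[keep, 1][o], pts[keep, 2][o])
  h <- grDevices::chull(survivors$x, survivors$y)
  hull <- contour(survivors$x[h], survivors$y[h])
  sm <- bezier_smooth(hull, smooth_params)
  # the pruning rule bounds the admissible radius; clip any smoothing overshoot
  dxs <- sm$x - previous_center[1]; dys <- previous_center[2] - sm$y
  rs <- sqrt(dxs^2 + dys^2)
  rmax <- fit$radius + outlier_px
  if (any(rs > rmax)) {
    sc <- pmin(1, rmax / pmax(rs, 1e-9))
    sm <- contour(previous_center[1] + dxs * sc, previous_center[2] - dys * sc)
  }
  sm
}
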