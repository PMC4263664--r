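# Blood-pool refinement: overlap-guided threshold selection and
# connected-component choice inside the ROI.

#' ROI specification
#'
#' A square ROI of side `2 * half_size + 1` centered at `center`
#' (0-based row, col in full-image coordinates). The center is clamped so
#' the ROI lies fully inside the image.
#'
#' @param center numeric `(row, col)`, 0-based, full-image frame.
#' @param half_size half side length in pixels (>= 16).
#' @param image_dim integer `(nrow, ncol)` of the full image.
#' @return list of class `lv_roi` with fields `center`, `half_size`,
#'   `row0`, `col0` (0-based offsets of the ROI's first pixel).
#' @export
roi_spec <- function(center, half_size, image_dim) {
  if (half_size < 16) stop("half_size must be at least 16")
  if (2 * half_size + 1 > min(image_dim)) stop("ROI larger than image")
  r <- clamp(round(center[1]), half_size, image_dim[1] - 1 - half_size)
  c <- clamp(round(center[2]), half_size, image_dim[2] - 1 - half_size)
  structure(list(center = c(r, c), half_size = as.integer(half_size),
                 row0 = as.integer(r - half_size), col0 = as.integer(c - half_size)),
            class = "lv_roi")
}

roi_crop <- function(image, roi) {
  image[(roi$row0 + 1):(roi$row0 + 2 * roi$half_size + 1),
        (roi$col0 + 1):(roi$col0 + 2 * roi$half_size + 1)]
}

# Shift a full-frame contour into ROI coordinates (and back).
contour_to_roi <- function(ct, roi) contour(ct$x - roi$col0, ct$y - roi$row0, orient = FALSE)
contour_to_full <- function(ct, roi) contour(ct$x + roi$col0, ct$y + roi$row0, orient = FALSE)

#' Initialisation mask for the LBF model
#'
#' At the mid slice the mask is a filled circle of `init_radius` pixels at
#' the ROI center; at every other slice it is the endocardial region
#' segmented from the previous slice, re-centered into the current ROI
#' (the ROI itself is placed at that region's centroid by the pipeline, so
#' cropping performs the transport).
#'
#' @param roi an [roi_spec()].
#' @param previous_region full-frame logical mask of the previous slice's
#'   endocardial region, or `NULL` at the mid slice.
#' @param init_radius circle radius in pixels (mid slice only); the default
#'   must sit inside the end-systolic mid-ventricular cavity.
#' @return logical ROI-frame mask.
#' @export
make_contour_mask <- function(roi, previous_region = NULL, init_radius = 10) {
  side <- 2 * roi$half_size + 1
  if (is.null(previous_region)) {
    return(disc_mask(c(side, side), c(roi$half_size, roi$half_size), init_radius))
  }
  m <- roi_crop(previous_region, roi)
  if (!any(m)) stop("previous endocardial region is empty in the current ROI")
  m
}

# Otsu threshold of a numeric matrix in its own intensity units.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)), range = c(0, 1)) * diff(rng) + rng[1]
}

#' Overlap-maximising threshold selection
#'
#' For each candidate threshold the ROI is binarised at `roi_image >= t`;
#' the 8-connected component with the largest overlap against `lbf_region`
#' is taken as that candidate's blood-pool hypothesis and its overlap is
#' recorded. The chosen threshold maximises the overlap curve; ties (a
#' plateau of equal overlap) are broken toward the candidate nearest the
#' Otsu threshold of the ROI. Overlap is the Dice coefficient between the
#' component and the LBF region by default; `metric = "intersection"` gives
#' the raw pixel-count intersection.
#'
#' @param roi_image numeric ROI intensity matrix.
#' @param lbf_region non-empty logical matrix from [run_lbf()].
#' @param candidates ascending numeric thresholds; default 24 evenly spaced
#'   values between the ROI's 5th and 95th intensity percentiles.
#' @param n_thresholds size of the default candidate grid.
#' @param metric `"dice"` (default) or `"intersection"`.
#' @return list of class `lv_threshold_search`: `candidates`, `chosen`,
#'   `overlap_curve`, `otsu`.
#' @export
optimal_threshold <- function(roi_image, lbf_region, candidates = NULL,
                              n_thresholds = 24, metric = c("dice", "intersection")) {
  metric <- match.arg(metric)
  if (!any(lbf_region)) stop("lbf_region is empty")
  if (is.null(candidates)) {
    q <- stats::quantile(roi_image, c(0.05, 0.95), names = FALSE)
    candidates <- seq(q[1], q[2], length.out = n_thresholds)
  }
  if (is.unsorted(candidates)) stop("candidates must be ascending")
  nlbf <- sum(lbf_region)
  overlap <- vapply(candidates, function(t) {
    bw <- roi_image >= t
    if (!any(bw)) return(0)
    lab <- label_components8(bw)
    inter <- tabulate(lab[lbf_region & bw], nbins = max(lab))
    if (!length(inter) || max(inter) == 0) return(0)
    best <- which.max(inter)
    if (metric == "intersection") inter[best]
    else 2 * inter[best] / (nlbf + sum(lab == best))
  }, numeric(1))
  if (all(overlap == 0)) stop("blood pool not found: no threshold yields overlap with the LBF region")
  ot <- otsu_threshold(roi_image)
  best <- which(overlap >= max(overlap) - 1e-12)
  chosen <- candidates[best[which.min(abs(candidates[best] - ot))]]
  structure(list(candidates = candidates, chosen = chosen,
                 overlap_curve = overlap, otsu = ot),
            class = "lv_threshold_search")
}

#' Extract the refined blood pool
#'
#' Binarises the ROI at the chosen threshold, labels 8-connected components,
#' keeps the single component with maximal overlap against the LBF region
#' and fills its holes (papillary muscles belong inside the cavity).
#'
#' @inheritParams optimal_threshold
#' @param search optional precomputed [optimal_threshold()] result.
#' @return logical ROI-frame mask (one 8-connected, hole-free component),
#'   with attributes `threshold` and `search`.
#' @export
extract_blood_pool <- function(roi_image, lbf_region, candidates = NULL,
                               n_thresholds = 24, metric = c("dice", "intersection"),
                               search = NULL) {
  metric <- match.arg(metric)
  if (is.null(search))
    search <- optimal_threshold(roi_image, lbf_region, candidates, n_thresholds, metric)
  bw <- roi_image >= search$chosen
  lab <- label_components8(bw)
  inter <- tabulate(lab[lbf_region & bw], nbins = max(lab))
  best <- which.max(inter)
  pool <- fill_holes(lab == best)
  attr(pool, "threshold") <- search$chosen
  attr(pool, "search") <- search
  pool
}
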