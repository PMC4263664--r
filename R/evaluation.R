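# Challenge-style evaluation metrics and clinical indices.
#
# A contour is "good" when its average perpendicular distance (APD) to the
# expert contour is below 5 mm; APD and Dice are summarised over good
# contours only, matching the challenge evaluation tool. Volumes are
# slice-summation (area x slice spacing); ejection fraction and myocardial
# mass follow the standard definitions.

#' Average perpendicular distance between contours
#'
#' Mean, over the automatic contour's vertices, of the minimal distance to
#' the expert polyline (point-to-segment, every segment of the closed
#' polygon considered), scaled to millimetres. One-directional
#' (auto -> manual) by default, per the challenge convention; `symmetric`
#' averages both directions.
#'
#' @param auto,manual [contour()] objects in the same image frame.
#' @param pixel_spacing_mm millimetres per pixel (scalar, or `(row, col)`
#'   whose mean is used).
#' @param symmetric average the two directed distances.
#' @return distance in mm.
#' @export
average_perpendicular_distance <- function(auto, manual, pixel_spacing_mm = 1,
                                           symmetric = FALSE) {
  sp <- mean(pixel_spacing_mm)
  d1 <- mean(point_polyline_distance(auto$x, auto$y, manual))
  if (!symmetric) return(d1 * sp)
  d2 <- mean(point_polyline_distance(manual$x, manual$y, auto))
  (d1 + d2) / 2 * sp
}

# Minimal distances from points to a closed polyline (vectorised over segments).
point_polyline_distance <- function(px, py, ct) {
  x1 <- ct$x; y1 <- ct$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    t <- ((px[i] - x1) * ex + (py[i] - y1) * ey) / pmax(len2, 1e-12)
    t <- clamp(t, 0, 1)
    out[i] <- sqrt(min((px[i] - (x1 + t * ex))^2 + (py[i] - (y1 + t * ey))^2))
  }
  out
}

#' Good-contour rule and percentage
#'
#' A contour is good when APD < 5 mm (strict). `percent_good` is the share
#' of good contours among all evaluated pairs, in percent.
#'
#' @param auto,manual contours; or for `percent_good` a numeric vector of
#'   APDs in mm (or a logical vector of good flags).
#' @param pixel_spacing_mm millimetres per pixel.
#' @param threshold_mm the rule's threshold.
#' @export
good_contour <- function(auto, manual, pixel_spacing_mm = 1, threshold_mm = 5) {
  average_perpendicular_distance(auto, manual, pixel_spacing_mm) < threshold_mm
}

#' @rdname good_contour
#' @param apd numeric APDs in mm, or logical good flags.
#' @export
percent_good <- function(apd, threshold_mm = 5) {
  if (!length(apd)) stop("no contour pairs to summarise")
  good <- if (is.logical(apd)) apd else apd < threshold_mm
  100 * sum(good) / length(good)
}

#' Dice overlap of two contours or masks
#'
#' `2|A n B| / (|A| + |B|)`. Contours are rasterised to filled regions on a
#' common grid first.
#'
#' @param a,b logical masks on the same grid, or contours.
#' @param dim grid `(nrow, ncol)` used when rasterising contours; default
#'   tightly covers both.
#' @export
dice <- function(a, b, dim = NULL) {
  if (is_contour(a) || is.data.frame(a)) {
    a <- contour(a); b <- contour(b)
    if (is.null(dim)) {
      dim <- c(ceiling(max(a$y, b$y)) + 2, ceiling(max(a$x, b$x)) + 2)
    }
    a <- contour_mask(a, dim); b <- contour_mask(b, dim)
  }
  dice_masks(a, b)
}

#' Slice-summation cavity volume
#'
#' `sum over slices of (enclosed area [px^2] x pixel_area [mm^2]) x
#' slice_spacing [mm] / 1000`, in millilitres. Enclosed area is the exact
#' (shoelace) polygon area.
#'
#' @param contours list of [contour()]s, one per slice (failed slices
#'   omitted).
#' @param pixel_spacing_mm `(row_mm, col_mm)` or scalar.
#' @param slice_spacing_mm center-to-center slice distance.
#' @return volume in mL.
#' @export
cavity_volume <- function(contours, pixel_spacing_mm, slice_spacing_mm) {
  if (!length(contours)) stop("no contours")
  if (is.null(pixel_spacing_mm) || is.null(slice_spacing_mm) ||
      any(!is.finite(c(pixel_spacing_mm, slice_spacing_mm))))
    stop("missing pixel or slice spacing")
  sp <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
  px_area <- sp[1] * sp[2]
  areas <- vapply(contours, function(ct) contour_area(contour(ct)), numeric(1))
  sum(areas) * px_area * slice_spacing_mm / 1000
}

#' Volume set for the clinical indices
#'
#' @param endo_ED,epi_ED,endo_ES volumes in mL (`epi_ED >= endo_ED >= 0`).
#' @param epi_ES optional.
#' @return list of class `lv_volumes`.
#' @export
volume_set <- function(endo_ED, epi_ED, endo_ES, epi_ES = NA_real_) {
  if (endo_ED < 0 || epi_ED < endo_ED) stop("need epi_ED >= endo_ED >= 0")
  structure(list(endo_ED = endo_ED, epi_ED = epi_ED, endo_ES = endo_ES,
                 epi_ES = epi_ES),
            class = "lv_volumes")
}

#' Ejection fraction
#'
#' `(EDV - ESV) / EDV x 100`, in percent.
#'
#' @param vols an [volume_set()] (or the EDV when `endo_ES` is given).
#' @param endo_ES ESV in mL when `vols` is a number.
#' @export
ejection_fraction <- function(vols, endo_ES = NULL) {
  if (is.numeric(vols)) vols <- list(endo_ED = vols, endo_ES = endo_ES)
  if (!is.finite(vols$endo_ED) || vols$endo_ED <= 0)
    stop("end-diastolic volume must be positive")
  (vols$endo_ED - vols$endo_ES) / vols$endo_ED * 100
}

#' Left-ventricular mass
#'
#' Myocardial volume at end-diastole (`epi_ED - endo_ED`) times tissue
#' density, in grams. The default density is 1.05 g/mL.
#'
#' @param vols an [volume_set()].
#' @param density_g_per_mL myocardial density.
#' @export
lv_mass <- function(vols, density_g_per_mL = 1.05) {
  myo <- vols$epi_ED - vols$endo_ED
  if (!is.finite(myo) || myo < 0) stop("negative myocardial volume")
  myo * density_g_per_mL
}

#' Regression and Bland-Altman agreement
#'
#' Ordinary least-squares fit of the automatic values on the expert values,
#' the coefficient of determination, and Bland-Altman bias
#' (`mean(auto - expert)`) with 1.96 SD limits of agreement.
#'
#' @param auto,expert numeric vectors of equal length >= 3.
#' @return list of class `lv_agreement`: `slope`, `intercept`, `r_squared`,
#'   `bias`, `loa_lower`, `loa_upper`, `n`, `data`.
#' @export
agreement_stats <- function(auto, expert) {
  if (length(auto) != length(expert) || length(auto) < 3)
    stop("need equal-length vectors with at least 3 values")
  if (stats::sd(expert) < 1e-12) stop("expert values have zero variance")
  fit <- stats::lm(auto ~ expert)
  diffs <- auto - expert
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((auto - mean(auto))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    bias = mean(diffs),
    loa_lower = mean(diffs) - 1.96 * stats::sd(diffs),
    loa_upper = mean(diffs) + 1.96 * stats::sd(diffs),
    n = length(auto),
    data = tibble::tibble(auto = auto, expert = expert)
  ), class = "lv_agreement")
}

#' Evaluate automatic against expert contours
#'
#' Takes a tibble of contour pairs and returns per-pair APD, Dice and the
#' good-contour flag. Pairs with a missing expert contour (e.g. the omitted
#' ES epicardial ground truth) are dropped.
#'
#' @param pairs tibble with list-columns `auto`, `manual` and a numeric
#'   `pixel_spacing_mm` column (recycled if scalar); other columns pass
#'   through.
#' @param threshold_mm good-contour threshold.
#' @return the input tibble with `apd_mm`, `dice`, `good` appended.
#' @export
evaluate_contour_pairs <- function(pairs, threshold_mm = 5) {
  keep <- !vapply(pairs$manual, is.null, logical(1)) &
    !vapply(pairs$auto, is.null, logical(1))
  pairs <- pairs[keep, ]
  if (!nrow(pairs)) stop("no contour pairs to evaluate")
  sp <- rep(pairs$pixel_spacing_mm %||% 1, length.out = nrow(pairs))
  pairs$apd_mm <- purrr::map2_dbl(pairs$auto, pairs$manual,
                                  ~ average_perpendicular_distance(.x, .y, 1)) * sp
  pairs$dice <- purrr::map2_dbl(pairs$auto, pairs$manual, ~ dice(.x, .y))
  pairs$good <- pairs$apd_mm < threshold_mm
  pairs
}

#' Pooled evaluation summary
#'
#' Good-contour percentage over all pairs; mean APD and Dice over the good
#' contours only (the challenge convention).
#'
#' @param evaluated result of [evaluate_contour_pairs()], optionally grouped.
#' @return one-row tibble (per group) with `n`, `percent_good`,
#'   `mean_apd_mm`, `mean_dice`.
#' @export
summarise_evaluation <- function(evaluated) {
  dplyr::summarise(evaluated,
                   n = dplyr::n(),
                   percent_good = percent_good(.data$apd_mm),
                   mean_apd_mm = mean(.data$apd_mm[.data$good]),
                   mean_dice = mean(.data$dice[.data$good]),
                   .groups = "drop")
}
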