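# Epicardial boundary extraction: polar resampling of the ROI about the
# endocardial center, a non-maxima-suppressed gradient edge map, a search
# mask that starts outside the endocardium and excludes bright tissue
# (right ventricle, pericardial/abdominal fat) plus, when available, stays
# inside the dilated previous epicardial region, and a column-wise dynamic
# programme with a bounded row jump and a closure penalty tying the last
# column to the first.

#' Dynamic-programming parameters
#'
#' @param delta maximum row jump between adjacent columns (integer >= 1).
#'   The closure step from the last column back to the first is bounded by
#'   the same jump.
#' @param w weighting factor of the image feature in the step cost
#'   `w * (1 - F)`.
#' @param gamma closure penalty factor: `gamma * |row_N - row_1|` is added in
#'   the final column.
#' @return list of class `dp_params`.
#' @export
dp_params <- function(delta = 2, w = 1, gamma = 0.1) {
  stopifnot(delta >= 1, delta == round(delta), w > 0, gamma >= 0)
  structure(list(delta = as.integer(delta), w = w, gamma = gamma),
            class = "dp_params")
}

#' Polar transform of an ROI image
#'
#' Resamples the disk of radius `r_max` about `center` onto a rectangle:
#' row `i` maps radius `(i - 1) * radial_step`, column `j` maps angle
#' `2*pi*(j - 1)/N`, angles increasing counter-clockwise in image
#' coordinates (`x = cx + r cos(theta)`, `y = cy - r sin(theta)`).
#' Sampling is bilinear; coordinates outside the ROI are clamped to the
#' boundary value.
#'
#' @param roi_image numeric ROI matrix.
#' @param center numeric `(x, y)` pole, 0-based ROI frame, inside the ROI.
#' @param r_max maximal radius in pixels.
#' @param n_angles number of angular columns N (>= 36).
#' @param radial_step radial sampling step in pixels per row.
#' @return list of class `lv_polar`: `values` (M x N), `center`,
#'   `radial_step`, `angular_step`, `r_max`.
#' @export
polar_transform <- function(roi_image, center, r_max, n_angles = 180, radial_step = 1) {
  nr <- nrow(roi_image); nc <- ncol(roi_image)
  if (center[1] < 0 || center[1] > nc - 1 || center[2] < 0 || center[2] > nr - 1)
    stop("pole lies outside the ROI")
  if (r_max <= 0) stop("r_max must be positive")
  if (n_angles < 36) stop("n_angles must be at least 36")
  m <- as.integer(floor(r_max / radial_step)) + 1L
  rr <- (seq_len(m) - 1) * radial_step
  th <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  xs <- outer(rr, cos(th))  # M x N
  ys <- outer(rr, -sin(th))
  x <- clamp(center[1] + xs, 0, nc - 1)
  y <- clamp(center[2] + ys, 0, nr - 1)
  j0 <- clamp(floor(x), 0, nc - 2); i0 <- clamp(floor(y), 0, nr - 2)
  fx <- as.vector(x - j0); fy <- as.vector(y - i0)
  i0 <- as.vector(i0); j0 <- as.vector(j0)
  v00 <- roi_image[cbind(i0 + 1, j0 + 1)]
  v01 <- roi_image[cbind(i0 + 1, j0 + 2)]
  v10 <- roi_image[cbind(i0 + 2, j0 + 1)]
  v11 <- roi_image[cbind(i0 + 2, j0 + 2)]
  vals <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  structure(list(values = matrix(vals, m, n_angles), center = center,
                 radial_step = radial_step, angular_step = 2 * pi / n_angles,
                 r_max = r_max),
            class = "lv_polar")
}

# circular shift of columns (k > 0 shifts content left)
shift_cols <- function(m, k) {
  nc <- ncol(m)
  m[, ((seq_len(nc) - 1 + k) %% nc) + 1, drop = FALSE]
}
# row shift with replicate boundary
shift_rows <- function(m, k) {
  nr <- nrow(m)
  m[clamp(seq_len(nr) + k, 1, nr), , drop = FALSE]
}

#' Non-maxima-suppressed edge feature of a polar map
#'
#' Gradient magnitude of the polar image (central differences; periodic in
#' the angular direction, replicated radially), thinned by non-maxima
#' suppression along the quantised gradient direction (a value survives only
#' if it is strictly greater than the preceding neighbour and no smaller
#' than the following one along the gradient, so plateaus keep a single
#' row), then min-max normalised to [0, 1]. The first and last radial rows
#' are boundary artifacts and are zeroed.
#'
#' @param polar an [polar_transform()] result, M >= 3 rows.
#' @return M x N matrix in [0, 1], class `matrix`.
#' @export
edge_feature <- function(polar) {
  v <- polar$values
  m <- nrow(v)
  if (m < 3) stop("polar map needs at least 3 radial rows")
  gr <- (shift_rows(v, 1) - shift_rows(v, -1)) / 2            # d/d radius
  # one-sided differences at the radial ends: replicate padding would halve
  # the gradient there and leave a spurious ridge beside pure ramps
  gr[1, ] <- v[2, ] - v[1, ]
  gr[m, ] <- v[m, ] - v[m - 1, ]
  gc <- (shift_cols(v, 1) - shift_cols(v, -1)) / 2            # d/d angle (periodic)
  mag <- sqrt(gr^2 + gc^2)
  ang <- atan2(gr, gc) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  off <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  keep <- matrix(FALSE, m, ncol(v))
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    nb_next <- shift_cols(shift_rows(mag, d[1]), d[2])
    nb_prev <- shift_cols(shift_rows(mag, -d[1]), -d[2])
    keep <- keep | (sector == s & mag > nb_prev & mag >= nb_next)
  }
  f <- mag * keep
  f[1, ] <- 0; f[m, ] <- 0
  if (max(f) > 0) f <- (f - min(f)) / (max(f) - min(f))
  f
}

#' Search mask for the epicardial dynamic programme
#'
#' Admissible cells lie at least `margin` rows beyond the endocardial radius
#' of their column, are not bright (right ventricle / fat exclusion), and,
#' when a previous epicardial region is supplied, lie inside its dilated
#' polar footprint. Any fully blocked column is reopened at the two rows
#' just beyond the endocardial radius so a path always exists.
#'
#' @param dim integer `(M, N)` of the polar grid.
#' @param endo_radius_rows numeric length-N: endocardial radius of each
#'   column, in row units (1-based fractional rows).
#' @param bright_polar optional logical M x N exclusion map.
#' @param previous_epi_polar optional logical M x N map of the previous
#'   slice's epicardial region (already dilated by the caller or via
#'   `dilation_rows`).
#' @param margin rows between the endocardium and the first admissible cell.
#' @param dilation_rows extra rows by which `previous_epi_polar` is dilated
#'   radially before use.
#' @return logical M x N matrix, every column containing >= 1 admissible row.
#' @export
build_search_mask <- function(dim, endo_radius_rows, bright_polar = NULL,
                              previous_epi_polar = NULL, margin = 1,
                              dilation_rows = 2) {
  m <- dim[1]; n <- dim[2]
  if (length(endo_radius_rows) != n) stop("endo_radius_rows must have one entry per column")
  first_row <- clamp(ceiling(endo_radius_rows) + margin, 1, m)
  B <- outer(seq_len(m), first_row, `>=`)
  if (!is.null(bright_polar)) B <- B & !bright_polar
  if (!is.null(previous_epi_polar)) {
    prev <- previous_epi_polar
    if (dilation_rows > 0) {
      for (k in seq_len(dilation_rows)) prev <- prev | shift_rows(previous_epi_polar, k) |
          shift_rows(previous_epi_polar, -k)
    }
    B <- B & prev
  }
  for (j in which(colSums(B) == 0)) {
    rows <- clamp(first_row[j] + c(0L, 1L), 1, m)
    B[rows, j] <- TRUE
  }
  B
}

#' Region-constrained closed-path dynamic programme
#'
#' Step cost `w * (1 - F)` on admissible cells, an infinite barrier
#' elsewhere. Paths move at most `delta` rows between adjacent columns and
#' must close with `|row_N - row_1| <= delta`; the final column is augmented
#' by the closure penalty `gamma * |row_N - row_1|`, applied exactly by
#' running one sweep per admissible first-column row. The optimum is the
#' minimal augmented cost over all (start, end) pairs; ties are broken
#' toward the smaller row index at every minimisation (including
#' backtracking).
#'
#' @param feature M x N edge-feature matrix in [0, 1].
#' @param mask logical M x N admissibility mask.
#' @param params an [dp_params()].
#' @return list of class `lv_costmap`: `C` (accumulated costs of the winning
#'   sweep), `predecessor`, `path` (length-N row indices), `cost` (total
#'   augmented cost).
#' @export
dp_optimal_path <- function(feature, mask, params = dp_params()) {
  m <- nrow(feature); n <- ncol(feature)
  if (!all(dim(mask) == c(m, n))) stop("feature and mask must share dimensions")
  delta <- params$delta
  step <- params$w * (1 - feature)
  step[!mask] <- Inf
  offsets <- (-delta):delta
  starts <- which(is.finite(step[, 1]))
  if (!length(starts)) stop("epicardium search infeasible: no admissible start")
  best <- list(cost = Inf)
  rows <- seq_len(m)
  for (s in starts) {
    C <- matrix(Inf, m, n)
    P <- matrix(NA_integer_, m, n)
    C[s, 1] <- step[s, 1]
    for (j in 2:n) {
      prev <- C[, j - 1]
      cand <- vapply(offsets, function(o) {
        src <- rows + o
        out <- rep(Inf, m)
        ok <- src >= 1 & src <= m
        out[ok] <- prev[src[ok]]
        out
      }, numeric(m))
      pick <- max.col(-cand, ties.method = "first")
      C[, j] <- cand[cbind(rows, pick)] + step[, j]
      P[, j] <- rows + offsets[pick]
    }
    # hard closure: last row within delta of the start row
    A <- C[, n] + params$gamma * abs(rows - s)
    A[abs(rows - s) > delta] <- Inf
    if (any(is.finite(A))) {
      e <- which.min(A)  # first minimum = smallest row
      if (A[e] < best$cost - 1e-15) best <- list(cost = A[e], s = s, e = e, C = C, P = P)
    }
  }
  if (!is.finite(best$cost)) stop("epicardium search infeasible: no closed path")
  path <- integer(n)
  path[n] <- best$e
  for (j in n:2) path[j - 1] <- best$P[path[j], j]
  structure(list(C = best$C, predecessor = best$P, path = path, cost = best$cost),
            class = "lv_costmap")
}

#' Cartesian epicardial contour from a DP path
#'
#' Inverse polar mapping of the per-column optimal rows back to (x, y)
#' coordinates; `offset` shifts the ROI frame into full-image coordinates.
#'
#' @param costmap an [dp_optimal_path()] result.
#' @param polar the [polar_transform()] the path was computed on.
#' @param offset numeric `(x, y)` added to the ROI coordinates.
#' @return An [contour()].
#' @export
epicardial_contour <- function(costmap, polar, offset = c(0, 0)) {
  n <- length(costmap$path)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- (costmap$path - 1) * polar$radial_step
  contour(polar$center[1] + r * cos(th) + offset[1],
          polar$center[2] - r * sin(th) + offset[2])
}
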