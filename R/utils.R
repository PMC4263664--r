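# Internal geometry and mask helpers shared across modules.
#
# Coordinate conventions (package-wide):
#  * images are R matrices indexed [row, col], 1-based;
#  * contour coordinates are 0-based with x = column - 1, y = row - 1 and
#    pixel centers at integer coordinates;
#  * "counter-clockwise in image coordinates" means counter-clockwise as the
#    image is displayed (y axis pointing down), i.e. the shoelace sum
#    sum(x_i * y_{i+1} - x_{i+1} * y_i) is negative.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a contour
#'
#' A contour is a closed planar polygon stored as a tibble with columns
#' `x` (column coordinate) and `y` (row coordinate), both 0-based with pixel
#' centers at integers. The polygon is implicitly closed: the last vertex
#' connects back to the first. Orientation is normalised to counter-clockwise
#' in image coordinates (y pointing down).
#'
#' @param x,y numeric vertex coordinates, or `x` a two-column matrix /
#'   data frame holding them.
#' @param orient if `TRUE` (default) reorder vertices so the polygon is
#'   counter-clockwise in image coordinates.
#' @return A tibble of class `lv_contour` with columns `x`, `y`.
#' @export
contour <- function(x, y = NULL, orient = TRUE) {
  if (is.null(y)) {
    m <- as.data.frame(x)
    if (ncol(m) < 2L) stop("contour needs two coordinate columns")
    names(m)[1:2] <- c("x", "y")
    x <- m$x; y <- m$y
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("a contour needs at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("contour coordinates must be finite")
  # drop consecutive duplicates (including the closing duplicate, if present)
  keep <- c(TRUE, abs(diff(x)) > 1e-12 | abs(diff(y)) > 1e-12)
  x <- x[keep]; y <- y[keep]
  if (length(x) > 1L && abs(x[1] - x[length(x)]) < 1e-12 && abs(y[1] - y[length(y)]) < 1e-12) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3L) stop("a contour needs at least 3 distinct points")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  if (orient && shoelace_signed(out$x, out$y) > 0) out <- out[rev(seq_len(nrow(out))), ]
  class(out) <- c("lv_contour", class(tibble::tibble()))
  out
}

#' @export
is_contour <- function(x) inherits(x, "lv_contour")

# Signed shoelace sum; negative = counter-clockwise in image coordinates.
shoelace_signed <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Enclosed polygon area
#'
#' Absolute shoelace area of a contour, in pixel^2 units.
#'
#' @param ct an [contour()] object.
#' @return numeric scalar.
#' @export
contour_area <- function(ct) abs(shoelace_signed(ct$x, ct$y))

contour_centroid <- function(ct) {
  x <- ct$x; y <- ct$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-9) return(c(x = mean(x), y = mean(y)))
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Rasterise a contour to a binary mask
#'
#' Even-odd (crossing number) polygon fill over pixel centers. A pixel at
#' matrix position `[i, j]` has center `(x = j - 1, y = i - 1)`.
#'
#' @param ct an [contour()] object.
#' @param dim integer vector `c(nrow, ncol)` of the target mask.
#' @return logical matrix.
#' @export
contour_mask <- function(ct, dim) {
  nr <- dim[1]; nc <- dim[2]
  x <- ct$x; y <- ct$y
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  mask <- matrix(FALSE, nr, nc)
  xs <- 0:(nc - 1)
  for (i in seq_len(nr)) {
    yc <- i - 1
    # half-open edge rule avoids double-counting vertices
    hit <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
    if (!any(hit)) next
    t <- (yc - y[hit]) / (y2[hit] - y[hit])
    xint <- sort(x[hit] + t * (x2[hit] - x[hit]))
    # pixel center is inside when an odd number of intersections lie to its left
    cross <- findInterval(xs, xint)
    mask[i, ] <- (cross %% 2L) == 1L
  }
  mask
}

# Boundary pixels of a mask (pixels with at least one 4-neighbour outside).
mask_boundary <- function(mask) {
  m <- mask
  up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
  # image-border foreground pixels count as boundary
  interior <- up & dn & lf & rt
  interior[1, ] <- FALSE; interior[nrow(m), ] <- FALSE
  interior[, 1] <- FALSE; interior[, ncol(m)] <- FALSE
  mask & !interior
}

# 0-based (x, y) coordinates of TRUE pixels.
mask_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# 8-connected component labelling (igraph backs the union-find; EBImage's
# bwlabel is 4-connected, which merges fewer pixels than this module needs).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[nidx] > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[nidx][hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Fill interior holes of a binary mask.
fill_holes <- function(mask) {
  EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask))) > 0.5
}

# Morphological dilation by a disc of the given radius (pixels).
dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
  EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)), brush) > 0.5
}

# Rasterised disc mask; center is 0-based (x, y).
disc_mask <- function(dim, center, radius) {
  xs <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  ys <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical matrices on the same grid.
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice_masks <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share dimensions")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("dice undefined: both masks empty")
  2 * sum(a & b) / (sa + sb)
}

# Exhaustive segment-intersection simplicity check (test-grade; <= ~400 vertices).
is_simple_polygon <- function(ct) {
  x <- ct$x; y <- ct$y; n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_int <- function(i, j) {
    d1 <- c(x2[i] - x[i], y2[i] - y[i]); d2 <- c(x2[j] - x[j], y2[j] - y[j])
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((x[j] - x[i]) * d2[2] - (y[j] - y[i]) * d2[1]) / den
    u <- ((x[j] - x[i]) * d1[2] - (y[j] - y[i]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == (i %% n) + 1 || i == (j %% n) + 1) next
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

# Piecewise-linear resampling of a star-shaped contour to radii at N uniform
# angles about `center` (0-based x, y). Angles follow the package polar
# convention: theta_j = 2*pi*(j-1)/N, x = cx + r cos(theta), y = cy - r sin(theta).
resample_radii <- function(ct, center, n) {
  dx <- ct$x - center[1]; dy <- center[2] - ct$y
  th <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # periodic extension for interpolation across the wrap
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r_ext <- c(r[length(r)], r, r[1])
  target <- 2 * pi * (0:(n - 1)) / n
  stats::approx(th_ext, r_ext, xout = target, ties = mean)$y
}

# Rebuild a contour from radii sampled at N uniform angles about center.
contour_from_radii <- function(radii, center) {
  n <- length(radii)
  th <- 2 * pi * (0:(n - 1)) / n
  contour(center[1] + radii * cos(th), center[2] - radii * sin(th))
}

# Restore RNG state on exit; gives generators local, seedable determinism.
with_preserved_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
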