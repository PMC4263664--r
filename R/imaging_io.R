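# Study and contour input/output.
#
# Studies are read from the package's plain fixture format: a directory of
# 16-bit grayscale TIFF files plus a `metadata.yaml` sidecar that carries the
# acquisition geometry (pixel spacing, slice spacing, slice locations,
# phases). DICOM is deliberately not parsed here; export a study to this
# format with any DICOM toolchain and point read_study() at the directory.

#' Construct a single short-axis slice
#'
#' @param pixels numeric matrix of non-negative intensities, at least 32x32.
#' @param pixel_spacing numeric length-2, `(row_mm, col_mm)`, both positive.
#' @param slice_index integer position from base (0) to apex.
#' @param phase one of `"ED"`, `"ES"`, `"other"`.
#' @param slice_spacing_mm center-to-center distance to the adjacent slice.
#' @return An object of class `lv_slice`.
#' @export
slice_image <- function(pixels, pixel_spacing, slice_index = 0L,
                        phase = c("ED", "ES", "other"), slice_spacing_mm = 8) {
  phase <- match.arg(phase)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("slice pixels must be at least 32 x 32")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("slice pixels must be finite and non-negative")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two strictly positive values (row_mm, col_mm)")
  if (!is.finite(slice_spacing_mm) || slice_spacing_mm <= 0)
    stop("slice_spacing_mm must be strictly positive")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 slice_index = as.integer(slice_index), phase = phase,
                 slice_spacing_mm = as.numeric(slice_spacing_mm)),
            class = "lv_slice")
}

#' Construct a study from per-phase slice stacks
#'
#' @param slices named list of phases (`ED`, `ES`, ...), each a list of
#'   [slice_image()] objects ordered base to apex.
#' @param mid_index 1-based index of the mid-ventricular slice within each
#'   stack; default `floor(n/2) + 1` (the middle of the stack, i.e. 0-based
#'   index `floor(n/2)`). Override when the mid-cavity slice is known.
#' @return An object of class `lv_study`.
#' @export
lv_study <- function(slices, mid_index = NULL) {
  if (is.null(names(slices)) || any(!nzchar(names(slices))))
    stop("slices must be a named list of phases")
  for (ph in names(slices)) {
    st <- slices[[ph]]
    if (!length(st)) stop("phase ", ph, " has no slices")
    if (!all(vapply(st, inherits, logical(1), "lv_slice")))
      stop("phase ", ph, " contains non-slice elements")
    dims <- vapply(st, function(s) dim(s$pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("mixed image sizes within phase ", ph)
  }
  n <- lengths(slices)
  mid <- mid_index %||% (n %/% 2L + 1L)
  mid <- as.integer(rep(mid, length.out = length(slices)))
  names(mid) <- names(slices)
  if (any(mid < 1L | mid > n)) stop("mid_index out of range")
  structure(list(slices = slices, mid_index = mid), class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  cat("<lv_study>", paste0(names(x$slices), ":", lengths(x$slices), collapse = " "),
      " mid:", paste(x$mid_index, collapse = "/"), "\n")
  invisible(x)
}

#' Read a study from a fixture directory
#'
#' The directory must contain `metadata.yaml` with keys `pixel_spacing`
#' (row_mm, col_mm), `slice_spacing_mm`, and `slices`, a list of records with
#' `file` (16-bit grayscale TIFF), `phase`, `location` (mm along the long
#' axis, increasing base to apex) and optional `scale` (intensity units per
#' unit code value, default 65535). Slices are ordered by `location`,
#' never by file name.
#'
#' @param path directory.
#' @param phase `"all"` (default) or a single phase to load.
#' @param mid_index optional 1-based mid-slice override.
#' @return An [lv_study()].
#' @export
read_study <- function(path, phase = "all", mid_index = NULL) {
  meta_file <- file.path(path, "metadata.yaml")
  if (!file.exists(meta_file))
    stop("no metadata.yaml in ", path,
         " (DICOM series are not parsed; export to the TIFF+YAML fixture format)")
  meta <- yaml::read_yaml(meta_file)
  for (k in c("pixel_spacing", "slice_spacing_mm", "slices")) {
    if (is.null(meta[[k]])) stop("metadata.yaml is missing required field '", k, "'")
  }
  recs <- meta$slices
  if (!length(recs)) stop("no readable images listed in metadata.yaml")
  tab <- tibble::tibble(
    file = vapply(recs, function(r) as.character(r$file), character(1)),
    phase = vapply(recs, function(r) as.character(r$phase %||% "other"), character(1)),
    location = vapply(recs, function(r) as.numeric(r$location), numeric(1)),
    scale = vapply(recs, function(r) as.numeric(r$scale %||% 65535), numeric(1))
  )
  if (!identical(phase, "all")) tab <- tab[tab$phase == phase, ]
  if (!nrow(tab)) stop("no slices for phase ", phase)
  slices <- list()
  for (ph in unique(tab$phase)) {
    sub <- tab[tab$phase == ph, ]
    sub <- sub[order(sub$location), ]
    slices[[ph]] <- lapply(seq_len(nrow(sub)), function(i) {
      img <- tiff::readTIFF(file.path(path, sub$file[i]))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      slice_image(img * sub$scale[i], meta$pixel_spacing,
                  slice_index = i - 1L, phase = ph,
                  slice_spacing_mm = meta$slice_spacing_mm)
    })
  }
  lv_study(slices, mid_index = mid_index)
}

#' Write a study in the fixture format
#'
#' Intensities are stored as 16-bit TIFF code values; a per-slice `scale`
#' in the sidecar restores the original units (quantisation error is at most
#' `max(intensity) / 131070`).
#'
#' @param study an [lv_study()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  recs <- list()
  sp <- NULL; sl <- NULL
  for (ph in names(study$slices)) {
    for (i in seq_along(study$slices[[ph]])) {
      s <- study$slices[[ph]][[i]]
      sp <- s$pixel_spacing; sl <- s$slice_spacing_mm
      fn <- sprintf("slice_%s_%02d.tif", ph, i - 1L)
      scale <- max(s$pixels, 1)
      tiff::writeTIFF(s$pixels / scale, file.path(path, fn),
                      bits.per.sample = 16L)
      recs[[length(recs) + 1L]] <- list(file = fn, phase = ph,
                                        location = (i - 1) * s$slice_spacing_mm,
                                        scale = scale)
    }
  }
  yaml::write_yaml(list(pixel_spacing = as.numeric(sp), slice_spacing_mm = sl,
                        slices = recs),
                   file.path(path, "metadata.yaml"))
  invisible(path)
}

#' Read an expert-style contour file
#'
#' One point per line, two whitespace-separated decimals `"x y"`, 0-based
#' column/row coordinates (the challenge manual-contour convention).
#'
#' @param path text file.
#' @return An [contour()] (vertex order as in the file).
#' @export
read_contour_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("contour file has fewer than 3 points: ", path)
  pts <- matrix(NA_real_, length(lines), 2)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || any(is.na(val)))
      stop("malformed contour line ", i, " in ", path, ": '", lines[i], "'")
    pts[i, ] <- val
  }
  contour(pts[, 1], pts[, 2], orient = FALSE)
}

#' Write a contour file
#'
#' One `"x y"` line per vertex, fixed 6-decimal formatting (so a write/read
#' round trip preserves coordinates to 1e-6), no header.
#'
#' @param ct an [contour()].
#' @param path output file.
#' @export
write_contour_file <- function(ct, path) {
  if (!is_contour(ct)) ct <- contour(ct)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f", ct$x, ct$y), con)
  invisible(path)
}
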