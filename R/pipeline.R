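# Slice-by-slice orchestration: the mid slice is segmented first from a
# circular initialisation; two independent marches then proceed toward the
# base (LVOT detection enabled) and toward the apex, each propagating the
# previous slice's endocardial center, blood pool, endocardial region and
# epicardial region as context.

#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their defaults.
#' Any subset can be overridden via `...` or loaded from a flat YAML file
#' with [read_config()].
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `lv_config`.
#' @details
#' * `roi_half_size` (40 px), `init_circle_radius` (10 px; must sit inside
#'   the end-systolic mid-cavity), `mid_index`
#'   (NULL = middle of the stack)
#' * LBF: `lambda1`, `lambda2` (1), `sigma` (3 px), `nu` (NULL =
#'   `0.003 * range^2`), `mu` (1), `timestep` (0.1), `epsilon` (1),
#'   `max_iter` (300), `tol` (1e-3)
#' * thresholding: `n_thresholds` (24), `overlap_metric` ("dice")
#' * endocardium: `lvot_ratio_threshold` (1.2), `pool_dilation_px` (3),
#'   `circle_outlier_px` (3), `min_pool_area` (20 px)
#' * epicardium: `n_angles` (180), `radial_step` (1 px), `delta` (2),
#'   `w` (1), `gamma` (0.1), `endo_margin_rows` (1), `r_max_factor` (2.5),
#'   `epi_dilation_px` (3), `bright_exclusion` (TRUE)
#' * smoothing: `keep_harmonics` (8), `bezier_segments` (12),
#'   `bezier_samples` (180), `smoothing_assignment`
#'   ("fft_endo_bezier_epi" or "bezier_endo_fft_epi")
#' @export
lv_config <- function(...) {
  cfg <- list(
    roi_half_size = 40, init_circle_radius = 10, mid_index = NULL,
    lambda1 = 1, lambda2 = 1, sigma = 3, nu = NULL, mu = 1,
    timestep = 0.1, epsilon = 1, max_iter = 300, tol = 1e-3,
    n_thresholds = 24, overlap_metric = "dice",
    lvot_ratio_threshold = 1.2, pool_dilation_px = 3, circle_outlier_px = 3,
    min_pool_area = 20,
    n_angles = 180, radial_step = 1, delta = 2, w = 1, gamma = 0.1,
    endo_margin_rows = 1, r_max_factor = 2.5, epi_dilation_px = 3,
    bright_exclusion = TRUE,
    keep_harmonics = 8, bezier_segments = 12, bezier_samples = 180,
    smoothing_assignment = "fft_endo_bezier_epi"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "lv_config")
}

#' Read a flat key-value YAML configuration file
#'
#' @param path YAML file whose top-level keys match [lv_config()] names.
#' @return An `lv_config`.
#' @export
read_config <- function(path) do.call(lv_config, yaml::read_yaml(path))

cfg_lbf_params <- function(cfg) {
  lbf_params(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2, sigma = cfg$sigma,
             nu = cfg$nu, mu = cfg$mu, timestep = cfg$timestep,
             epsilon = cfg$epsilon, max_iter = cfg$max_iter, tol = cfg$tol)
}
cfg_smooth_params <- function(cfg) {
  smoothing_params(keep_harmonics = cfg$keep_harmonics,
                   bezier_segments = cfg$bezier_segments,
                   bezier_samples = cfg$bezier_samples)
}

#' Segment a single slice
#'
#' Executes ROI placement, LBF blood-pool localisation, overlap-guided
#' threshold refinement, the LVOT branch, endocardial contouring, polar
#' edge-map construction, the epicardial dynamic programme and contour
#' smoothing. Per-slice failures are caught and reported in the result
#' status, never raised.
#'
#' @param slice an [slice_image()].
#' @param context `NULL` at the mid slice, otherwise the previous slice's
#'   result (an `lv_slice_result`).
#' @param config an [lv_config()].
#' @param direction `"mid"`, `"base"` or `"apex"`; LVOT detection is only
#'   active marching toward the base.
#' @return list of class `lv_slice_result` with fields `status`
#'   (`ok`, `failed`, `skipped_small_pool`), `stage_failed`, `endo`, `epi`
#'   (full-frame contours), `blood_pool`, `endo_mask`, `epi_mask`
#'   (full-frame masks), `roi`, `lvot`, `threshold`, `center`,
#'   `hull_major_axis`.
#' @export
segment_slice <- function(slice, context = NULL, config = lv_config(),
                          direction = c("mid", "base", "apex")) {
  direction <- match.arg(direction)
  if (!inherits(slice, "lv_slice")) stop("slice must be an lv_slice")
  dim_full <- dim(slice$pixels)
  res <- list(status = "failed", stage_failed = NA_character_, endo = NULL,
              epi = NULL, blood_pool = NULL, endo_mask = NULL, epi_mask = NULL,
              roi = NULL, lvot = NULL, threshold = NA_real_, center = NULL,
              hull_major_axis = NA_real_, slice_index = slice$slice_index,
              phase = slice$phase)
  class(res) <- "lv_slice_result"
  stage <- "roi"
  out <- tryCatch({
    center_rc <- if (is.null(context)) (dim_full - 1) / 2 else
      c(context$center[2], context$center[1])  # (row, col) from (x, y)
    roi <- roi_spec(center_rc, config$roi_half_size, dim_full)
    roi_img <- roi_crop(slice$pixels, roi)
    res$roi <- roi

    stage <- "lbf"
    init <- make_contour_mask(roi, previous_region = context$endo_mask,
                              init_radius = config$init_circle_radius)
    lbf_all <- run_lbf(roi_img, init, cfg_lbf_params(config))
    # the binary object delivered by the LBF model is the component of
    # {phi > 0} that overlaps the initialisation mask
    lab <- label_components8(lbf_all)
    inter <- tabulate(lab[init & lbf_all], nbins = max(lab))
    if (!length(inter) || max(inter) == 0) stop("LBF region does not overlap the initialisation mask")
    lbf_region <- lab == which.max(inter)

    stage <- "blood_pool"
    pool <- extract_blood_pool(roi_img, lbf_region,
                               n_thresholds = config$n_thresholds,
                               metric = config$overlap_metric)
    res$threshold <- attr(pool, "threshold")
    if (sum(pool) < config$min_pool_area) {
      res$status <- "skipped_small_pool"
      res$stage_failed <- NA_character_
      return(res)
    }

    stage <- "lvot"
    hull0 <- endo_without_lvot(pool)
    hull_mask <- contour_mask(hull0, dim(pool))
    res$hull_major_axis <- major_axis_length(hull_mask)
    has_lvot <- FALSE
    if (direction == "base" && !is.null(context) && is.finite(context$hull_major_axis)) {
      res$lvot <- detect_lvot(res$hull_major_axis, context$hull_major_axis,
                              config$lvot_ratio_threshold)
      has_lvot <- res$lvot$has_lvot
    }

    stage <- "endocardium"
    sm <- cfg_smooth_params(config)
    if (has_lvot) {
      prev_pool_roi <- roi_crop(context$pool_mask, roi)
      if (!any(prev_pool_roi)) stop("previous blood pool empty in current ROI")
      prev_c_full <- context$center  # (x, y) full frame
      prev_center <- c(prev_c_full[1] - roi$col0, prev_c_full[2] - roi$row0)
      endo_roi <- endo_with_lvot(roi_img >= res$threshold, prev_pool_roi,
                                 prev_center,
                                 dilation_px = config$pool_dilation_px,
                                 outlier_px = config$circle_outlier_px,
                                 smooth_params = sm)
    } else {
      endo_roi <- hull0
      if (config$smoothing_assignment == "fft_endo_bezier_epi") {
        cen <- contour_centroid(endo_roi)
        radii <- resample_radii(endo_roi, cen, config$n_angles)
        endo_roi <- contour_from_radii(fft_smooth(radii, sm), cen)
      } else {
        endo_roi <- bezier_smooth(endo_roi, sm)
      }
    }
    endo_center <- contour_centroid(endo_roi)

    stage <- "polar"
    dxe <- endo_roi$x - endo_center[1]; dye <- endo_center[2] - endo_roi$y
    max_endo_r <- max(sqrt(dxe^2 + dye^2))
    r_max <- min(config$r_max_factor * max_endo_r,
                 endo_center[1] - 1, 2 * roi$half_size - 1 - endo_center[1],
                 endo_center[2] - 1, 2 * roi$half_size - 1 - endo_center[2])
    if (r_max <= max_endo_r + 2) r_max <- max_endo_r + 2
    polar <- polar_transform(roi_img, endo_center, r_max,
                             n_angles = config$n_angles,
                             radial_step = config$radial_step)

    stage <- "epicardium"
    feat <- edge_feature(polar)
    endo_rows <- resample_radii(endo_roi, endo_center, config$n_angles) /
      config$radial_step + 1
    bright_polar <- NULL
    if (isTRUE(config$bright_exclusion)) {
      bright <- slice$pixels >= res$threshold
      bright_roi <- roi_crop(bright, roi)
      bp <- polar_transform(bright_roi * 1, endo_center, r_max,
                            n_angles = config$n_angles,
                            radial_step = config$radial_step)
      bright_polar <- bp$values > 0.5
    }
    prev_epi_polar <- NULL
    if (!is.null(context) && !is.null(context$epi_mask)) {
      pe <- dilate_disc(roi_crop(context$epi_mask, roi), config$epi_dilation_px)
      pep <- polar_transform(pe * 1, endo_center, r_max,
                             n_angles = config$n_angles,
                             radial_step = config$radial_step)
      prev_epi_polar <- pep$values > 0.5
    }
    maskB <- build_search_mask(dim(feat), endo_rows, bright_polar,
                               prev_epi_polar, margin = config$endo_margin_rows)
    cm <- dp_optimal_path(feat, maskB,
                          dp_params(delta = config$delta, w = config$w,
                                    gamma = config$gamma))

    stage <- "smoothing"
    epi_roi <- epicardial_contour(cm, polar)
    if (config$smoothing_assignment == "fft_endo_bezier_epi") {
      epi_roi <- bezier_smooth(epi_roi, sm)
    } else {
      radii <- resample_radii(epi_roi, endo_center, config$n_angles)
      epi_roi <- contour_from_radii(fft_smooth(radii, sm), endo_center)
    }

    stage <- "containment"
    endo_full <- contour_to_full(endo_roi, roi)
    epi_full <- contour_to_full(epi_roi, roi)
    endo_mask <- contour_mask(endo_full, dim_full)
    epi_mask <- contour_mask(epi_full, dim_full)
    if (sum(endo_mask & !epi_mask) > 0.02 * sum(endo_mask))
      stop("epicardial region does not contain the endocardial region")
    epi_mask <- epi_mask | endo_mask

    pool_full <- matrix(FALSE, dim_full[1], dim_full[2])
    pool_full[(roi$row0 + 1):(roi$row0 + 2 * roi$half_size + 1),
              (roi$col0 + 1):(roi$col0 + 2 * roi$half_size + 1)] <- pool
    res$endo <- endo_full
    res$epi <- epi_full
    res$endo_mask <- endo_mask
    res$epi_mask <- epi_mask
    res$blood_pool <- pool_full
    res$pool_mask <- pool_full
    res$center <- c(endo_center[1] + roi$col0, endo_center[2] + roi$row0)
    res$status <- "ok"
    res
  }, error = function(e) {
    res$status <- "failed"
    res$stage_failed <- stage
    res$message <- conditionMessage(e)
    res
  })
  out
}

#' Segment a full study
#'
#' The mid slice of each phase is segmented first (its failure is a
#' study-level error, since nothing can be propagated); two independent
#' marches then run mid-to-base (with LVOT detection) and mid-to-apex
#' (without). A failed slice passes the last successful context forward.
#' ED and ES stacks are processed with identical parameters.
#'
#' @param study an [lv_study()] with at least 3 slices per phase.
#' @param config an [lv_config()].
#' @return list of class `lv_study_result`: `results` (per phase, a list of
#'   `lv_slice_result` ordered base to apex), `config`, `log` (tibble of
#'   per-slice decisions).
#' @export
segment_study <- function(study, config = lv_config()) {
  if (!inherits(study, "lv_study")) stop("study must be an lv_study")
  results <- list()
  logs <- list()
  for (ph in names(study$slices)) {
    stack <- study$slices[[ph]]
    n <- length(stack)
    if (n < 3) stop("need at least 3 slices per phase (phase ", ph, " has ", n, ")")
    mid <- config$mid_index %||% study$mid_index[[ph]]
    out <- vector("list", n)
    mid_res <- segment_slice(stack[[mid]], context = NULL, config = config,
                             direction = "mid")
    if (mid_res$status != "ok")
      stop("mid-slice segmentation failed in phase ", ph,
           " at stage '", mid_res$stage_failed, "': nothing to propagate")
    out[[mid]] <- mid_res
    ctx <- mid_res
    if (mid > 1) for (i in (mid - 1):1) {           # march toward the base
      out[[i]] <- segment_slice(stack[[i]], context = ctx, config = config,
                                direction = "base")
      if (out[[i]]$status == "ok") ctx <- out[[i]]
    }
    ctx <- mid_res                                   # context isolation
    if (mid < n) for (i in (mid + 1):n) {            # march toward the apex
      out[[i]] <- segment_slice(stack[[i]], context = ctx, config = config,
                                direction = "apex")
      if (out[[i]]$status == "ok") ctx <- out[[i]]
    }
    results[[ph]] <- out
    logs[[ph]] <- tibble::tibble(
      phase = ph,
      slice_index = vapply(out, function(r) r$slice_index, integer(1)),
      status = vapply(out, function(r) r$status, character(1)),
      stage_failed = vapply(out, function(r) r$stage_failed %||% NA_character_, character(1)),
      has_lvot = vapply(out, function(r) isTRUE(r$lvot$has_lvot), logical(1)),
      threshold = vapply(out, function(r) r$threshold %||% NA_real_, numeric(1))
    )
  }
  structure(list(results = results, config = config,
                 log = dplyr::bind_rows(logs)),
            class = "lv_study_result")
}

#' Write study-result contours as challenge-style text files
#'
#' One file per slice per surface, named
#' `<phase>-<slice>-<icontour|ocontour>-auto.txt`.
#'
#' @param result an [segment_study()] result.
#' @param path output directory.
#' @return tibble of written files, invisibly.
#' @export
write_result_contours <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ph in names(result$results)) {
    for (r in result$results[[ph]]) {
      if (r$status != "ok") next
      surfaces <- c(icontour = "endo", ocontour = "epi")
      for (tag in names(surfaces)) {
        ct <- r[[surfaces[[tag]]]]
        fn <- sprintf("%s-%02d-%s-auto.txt", ph, r$slice_index, tag)
        write_contour_file(ct, file.path(path, fn))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phase = ph, slice_index = r$slice_index, surface = surfaces[[tag]],
          file = fn)
      }
    }
  }
  invisible(dplyr::bind_rows(rows))
}
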