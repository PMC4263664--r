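# Deterministic synthetic cine-MR phantom. Emulates the features the
# segmentation pipeline must cope with: a bright LV blood pool inside a
# darker myocardial annulus, background brighter than myocardium (the
# epicardial edge is the weaker one), an adjacent bright RV crescent,
# a pericardial fat arc touching the epicardium, radii tapering from base
# to apex, an optional outflow-tract (LVOT) opening at the basal slice
# where cavity-bright signal breaches the wall, plus seeded additive
# Gaussian noise and a smooth multiplicative polynomial bias field.

#' Phantom specification
#'
#' @param n_slices slices per phase, base to apex.
#' @param image_size square image side in pixels.
#' @param endo_radius_base,endo_radius_apex cavity radius at the basal /
#'   apical slice (ED), linear taper between.
#' @param wall_thickness myocardial wall in pixels (>= 2).
#' @param intensities named vector `pool`, `myocardium`, `background`,
#'   `rv_pool`, `fat`; must satisfy pool > background > myocardium.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bias_amplitude relative amplitude of the multiplicative bias field.
#' @param lvot add a basal outflow-tract opening.
#' @param lvot_arc_deg angular width of the opening.
#' @param es_scale factor applied to cavity radii in the ES phase
#'   (analytic ejection fraction `1 - es_scale^2`).
#' @param phases phases to generate.
#' @param pixel_spacing_mm,slice_spacing_mm acquisition geometry.
#' @param center_drift_px amplitude of the deterministic slice-to-slice
#'   in-plane drift of the LV center.
#' @param seed integer; fixed seed gives bit-identical output.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 8, image_size = 128,
                         endo_radius_base = 22, endo_radius_apex = 9,
                         wall_thickness = 7,
                         intensities = c(pool = 200, myocardium = 60,
                                         background = 110, rv_pool = 190,
                                         fat = 230),
                         noise_sd = 8, bias_amplitude = 0.1,
                         lvot = FALSE, lvot_arc_deg = 70, es_scale = 0.7,
                         phases = c("ED", "ES"),
                         pixel_spacing_mm = c(1.25, 1.25),
                         slice_spacing_mm = 9, center_drift_px = 2,
                         seed = 42) {
  if (wall_thickness < 2) stop("degenerate annulus: wall_thickness must be >= 2 px")
  ii <- intensities
  if (!(ii["pool"] > ii["background"] && ii["background"] > ii["myocardium"]))
    stop("intensities must satisfy pool > background > myocardium")
  if (endo_radius_apex > endo_radius_base) stop("radii must taper toward the apex")
  structure(as.list(environment()), class = "phantom_spec")
}

phantom_radius <- function(spec, i, phase) {
  r <- spec$endo_radius_base -
    (spec$endo_radius_base - spec$endo_radius_apex) * (i - 1) / (spec$n_slices - 1)
  if (phase == "ES") r <- r * spec$es_scale
  r
}

phantom_center <- function(spec, i) {
  c0 <- (spec$image_size - 1) / 2
  c(x = c0 + round(spec$center_drift_px * cos(0.9 * i)),
    y = c0 + round(spec$center_drift_px * sin(0.7 * i)))
}

# truth circle contour, 360 vertices, counter-clockwise in image coordinates
phantom_circle <- function(center, radius, n = 360) {
  th <- 2 * pi * (0:(n - 1)) / n
  contour(center[1] + radius * cos(th), center[2] - radius * sin(th))
}

#' Generate a phantom study with ground truth
#'
#' Builds the per-slice images (geometry, then multiplicative bias, then
#' seeded additive noise), the per-slice truth contours and masks (drawn
#' before noise), and the analytic volumes. The generated object is a stack
#' of constant-radius discs, so its closed-form volume is the slice
#' summation `sum(pi r_i^2) * slice_spacing` (the frustum/disc form); the
#' analytic ejection fraction of the two-phase default is exactly
#' `1 - es_scale^2`.
#'
#' At an LVOT basal slice the cavity-bright signal breaches the wall over
#' `lvot_arc_deg` degrees out to 2.1 cavity radii, so the blood pool's
#' convex-hull major axis exceeds the next slice's by construction (ratio
#' > 1.25). The truth endocardial contour remains the full cavity circle
#' (the challenge convention closes the contour across the outflow tract).
#'
#' @param spec an [phantom_spec()].
#' @return list of class `lv_phantom`: `study` ([lv_study()]), `truth`
#'   (tibble: phase, slice_index, endo/epi contours, endo/epi/pool masks),
#'   `analytic_volumes` ([volume_set()]), `spec`.
#' @export
generate_phantom_study <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sz <- spec$image_size
  ii <- spec$intensities
  xs <- matrix(0:(sz - 1), sz, sz, byrow = TRUE)
  ys <- matrix(0:(sz - 1), sz, sz)
  u <- 2 * xs / (sz - 1) - 1
  v <- 2 * ys / (sz - 1) - 1
  poly <- 0.5 * (u^2 - v^2) + 0.3 * u * v + 0.2 * u
  bias <- 1 + spec$bias_amplitude * poly / max(abs(poly))

  with_preserved_seed(spec$seed, {
    slices <- list(); truth <- list()
    for (ph in spec$phases) {
      stack <- vector("list", spec$n_slices)
      for (i in seq_len(spec$n_slices)) {
        cen <- phantom_center(spec, i)
        r_endo <- phantom_radius(spec, i, ph)
        r_epi <- r_endo + spec$wall_thickness
        d2 <- (xs - cen["x"])^2 + (ys - cen["y"])^2
        endo_mask <- d2 <= r_endo^2
        epi_mask <- d2 <= r_epi^2
        img <- matrix(ii["background"], sz, sz)
        img[epi_mask] <- ii["myocardium"]
        img[endo_mask] <- ii["pool"]
        # RV crescent: bright disc left of the LV, clipped outside the wall
        rv_c <- c(cen["x"] - (r_epi + 0.55 * r_epi), cen["y"])
        rv <- ((xs - rv_c[1])^2 + (ys - rv_c[2])^2 <= (0.8 * r_epi)^2) & !epi_mask
        img[rv] <- ii["rv_pool"]
        # pericardial fat arc hugging the epicardium away from the RV
        ang <- atan2(cen["y"] - ys, xs - cen["x"])
        fat <- d2 > r_epi^2 & d2 <= (r_epi + 3)^2 &
          ang > -100 * pi / 180 & ang < -30 * pi / 180
        img[fat] <- ii["fat"]
        pool_mask <- endo_mask
        if (spec$lvot && i == 1L) {
          half <- spec$lvot_arc_deg / 2 * pi / 180
          leak <- abs(ang) <= half & d2 <= (2.1 * r_endo)^2 & !endo_mask
          img[leak] <- ii["pool"]
          pool_mask <- endo_mask | leak
        }
        img <- img * bias
        if (spec$noise_sd > 0)
          img <- img + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
        img <- pmax(img, 0)
        stack[[i]] <- slice_image(img, spec$pixel_spacing_mm,
                                  slice_index = i - 1L, phase = ph,
                                  slice_spacing_mm = spec$slice_spacing_mm)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          phase = ph, slice_index = i - 1L,
          endo_radius = r_endo, epi_radius = r_epi,
          center_x = unname(cen["x"]), center_y = unname(cen["y"]),
          endo = list(phantom_circle(cen, r_endo)),
          epi = list(phantom_circle(cen, r_epi)),
          endo_mask = list(endo_mask), epi_mask = list(epi_mask),
          pool_mask = list(pool_mask))
      }
      slices[[ph]] <- stack
    }
    truth <- dplyr::bind_rows(truth)
    px_area <- prod(rep(spec$pixel_spacing_mm, length.out = 2))
    vol <- function(ph, which) {
      rr <- vapply(seq_len(spec$n_slices), function(i) {
        r <- phantom_radius(spec, i, ph)
        if (which == "epi") r <- r + spec$wall_thickness
        r
      }, numeric(1))
      sum(pi * rr^2) * px_area * spec$slice_spacing_mm / 1000
    }
    analytic <- volume_set(
      endo_ED = vol("ED", "endo"), epi_ED = vol("ED", "epi"),
      endo_ES = if ("ES" %in% spec$phases) vol("ES", "endo") else NA_real_,
      epi_ES = if ("ES" %in% spec$phases) vol("ES", "epi") else NA_real_)
    structure(list(study = lv_study(slices), truth = truth,
                   analytic_volumes = analytic, spec = spec),
              class = "lv_phantom")
  })
}
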