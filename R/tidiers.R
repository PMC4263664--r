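# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.lv_agreement <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.lv_agreement <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, bias = x$bias,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n)
}

#' @export
print.lv_agreement <- function(x, ...) {
  cat(sprintf("<lv_agreement> n=%d slope=%.4f intercept=%.3f R2=%.4f bias=%.3f LoA=[%.3f, %.3f]\n",
              x$n, x$slope, x$intercept, x$r_squared, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Regression or Bland-Altman plot of an agreement analysis
#'
#' @param object an [agreement_stats()] result.
#' @param type `"regression"` (auto vs expert with the OLS line and the
#'   identity) or `"bland_altman"` (differences vs means with bias and 1.96
#'   SD limits).
#' @param ... unused.
#' @export
autoplot.lv_agreement <- function(object, type = c("regression", "bland_altman"), ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "regression") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$expert, y = .data$auto)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "steelblue") +
      ggplot2::labs(x = "Expert", y = "Automatic",
                    subtitle = sprintf("slope %.3f, R² %.3f",
                                       object$slope, object$r_squared))
  } else {
    d2 <- tibble::tibble(m = (d$auto + d$expert) / 2, d = d$auto - d$expert)
    ggplot2::ggplot(d2, ggplot2::aes(x = .data$m, y = .data$d)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                          linetype = "dashed") +
      ggplot2::labs(x = "Mean of methods", y = "Difference (auto - expert)",
                    subtitle = sprintf("bias %.3f, LoA [%.3f, %.3f]",
                                       object$bias, object$loa_lower, object$loa_upper))
  }
}

#' @export
tidy.lv_study_result <- function(x, ...) x$log

#' @export
glance.lv_study_result <- function(x, ...) {
  tibble::tibble(
    n_slices = nrow(x$log),
    n_ok = sum(x$log$status == "ok"),
    n_failed = sum(x$log$status == "failed"),
    n_skipped = sum(x$log$status == "skipped_small_pool"),
    n_lvot = sum(x$log$has_lvot)
  )
}

#' @export
print.lv_study_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<lv_study_result> %d slices: %d ok, %d failed, %d skipped, %d LVOT\n",
              g$n_slices, g$n_ok, g$n_failed, g$n_skipped, g$n_lvot))
  invisible(x)
}

#' Plot segmented contours over a slice
#'
#' @param slice an [slice_image()].
#' @param result the matching `lv_slice_result`.
#' @param truth optional list with `endo`/`epi` truth contours.
#' @return a ggplot object.
#' @export
plot_slice_result <- function(slice, result, truth = NULL) {
  img <- slice$pixels
  d <- tibble::tibble(x = rep(0:(ncol(img) - 1), each = nrow(img)),
                      y = rep(0:(nrow(img) - 1), ncol(img)),
                      value = as.vector(img))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed()
  add_ct <- function(p, ct, colour) {
    if (is.null(ct)) return(p)
    cd <- tibble::tibble(x = c(ct$x, ct$x[1]), y = c(ct$y, ct$y[1]))
    p + ggplot2::geom_path(data = cd, ggplot2::aes(x = .data$x, y = .data$y),
                           colour = colour, inherit.aes = FALSE)
  }
  p <- add_ct(p, result$endo, "dodgerblue")
  p <- add_ct(p, result$epi, "orange")
  if (!is.null(truth)) {
    p <- add_ct(p, truth$endo, "red")
    p <- add_ct(p, truth$epi, "darkred")
  }
  p
}
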