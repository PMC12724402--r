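#' Plot a segmentation map
#'
#' @param object a `seg_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.seg_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "segment", x = NULL, y = NULL,
                  title = sprintf("Segmentation map (K = %d)", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot a perceptual uncertainty (entropy) map
#'
#' @param object an `entropy_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.entropy_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$entropy_bits)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, log2(object$K))) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "bits", x = NULL, y = NULL,
                  title = "Perceptual uncertainty") +
    ggplot2::theme_minimal()
}

#' Plot a probabilistic segmentation map, one facet per segment
#'
#' @param object a `prob_seg_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prob_seg_map <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            dplyr::starts_with("p"),
                            names_to = "segment", values_to = "prob")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~segment) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "P(label)", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ERP (one line per channel)
#'
#' @param object an `erp`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.erp <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uv,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a coverage curve
#'
#' @param curve tibble from [coverage_curve()] (optionally with a grouping
#'   column `cohort`).
#' @return a ggplot.
#' @export
plot_coverage_curve <- function(curve) {
  aes <- if ("cohort" %in% names(curve)) {
    ggplot2::aes(.data$window_s, .data$coverage_pct,
                 colour = .data$cohort, group = .data$cohort)
  } else {
    ggplot2::aes(.data$window_s, .data$coverage_pct)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cumulative window (s)", y = "image coverage (%)") +
    ggplot2::theme_minimal()
}

#' Plot a gaze density map
#'
#' @param density a `gaze_density`.
#' @return a ggplot.
#' @export
plot_gaze_density <- function(density) {
  M <- density$map
  df <- tibble::tibble(
    x = rep(seq_len(ncol(M)) - 1L, each = nrow(M)),
    y = rep(seq_len(nrow(M)) - 1L, times = ncol(M)),
    dwell_s = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, -.data$y,
                                   fill = .data$dwell_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "dwell (s)", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot GFP series with significance flags
#'
#' @param gfp_df tibble with `time_ms`, `gfp`, and optional `cohort`.
#' @param tests optional tibble from [gfp_interval_tests()].
#' @return a ggplot.
#' @export
plot_gfp <- function(gfp_df, tests = NULL) {
  aes <- if ("cohort" %in% names(gfp_df)) {
    ggplot2::aes(.data$time_ms, .data$gfp, colour = .data$cohort)
  } else {
    ggplot2::aes(.data$time_ms, .data$gfp)
  }
  p <- ggplot2::ggplot(gfp_df, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(tests) && any(tests$significant)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(tests[tests$significant, ], gfp = 0),
      mapping = ggplot2::aes(.data$time_ms, .data$gfp),
      inherit.aes = FALSE, shape = 8, colour = "red")
  }
  p
}

#' Plot a topographic frame
#'
#' @param frame tibble from [topomap_frame()].
#' @return a ggplot.
#' @export
plot_topomap <- function(frame) {
  ggplot2::ggplot(frame, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$display_uv)) +
    ggplot2::geom_point(size = 6) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red", limits = c(-10, 10)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "µV",
                  title = sprintf("t = %g ms", frame$time_ms[1])) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
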