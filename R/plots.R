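#' Plot an axial slice of a statistical map
#'
#' @param object An `isc_statmap`.
#' @param slice Axial (third-dimension) slice index; default the middle.
#' @param what `"statistic"`, `"p"` or `"significant"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isc_statmap <- function(object, slice = NULL,
                                 what = "statistic", ...) {
  vol <- statmap_volume(object, what)
  if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(dim(vol)[1]),
                           y = seq_len(dim(vol)[2]))
  df$value <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95",
                                  high = "firebrick", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, axial slice %d", what, slice),
                  fill = what) +
    ggplot2::theme_minimal()
}

#' Plot a framewise-displacement trace
#'
#' @param object An `fd_trace`.
#' @param ... Unused.
#' @return A ggplot object with the QC threshold marked.
#' @export
autoplot.fd_trace <- function(object, ...) {
  thr <- attr(object, "threshold_mm")
  ggplot2::ggplot(object, ggplot2::aes(.data$tr, .data$fd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "TR", y = "framewise displacement (mm)") +
    ggplot2::theme_minimal()
}

#' Plot one window of a gaze heatmap stack
#'
#' @param object A `gaze_heatmaps` object.
#' @param window Window index (default 1).
#' @param ... Unused.
#' @return A ggplot object in screen degrees.
#' @export
autoplot.gaze_heatmaps <- function(object, window = 1, ...) {
  g <- object$grids[, , window]
  nx <- nrow(g); ny <- ncol(g)
  df <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  df$x <- (df$ix - 0.5) * object$resolution - object$screen_extent[1] / 2
  df$y <- (df$iy - 0.5) * object$resolution - object$screen_extent[2] / 2
  df$density <- as.vector(g)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = sprintf("gaze heatmap, window %d", window)) +
    ggplot2::theme_minimal()
}

#' Plot an eISC window-by-pair matrix as group time courses
#'
#' @param object An `eisc_matrix`.
#' @param ... Unused.
#' @return A ggplot of the mean eISC per window and pair class.
#' @export
autoplot.eisc_matrix <- function(object, ...) {
  df <- tibble(window = rep(seq_len(nrow(object$z)), ncol(object$z)),
               pair_class = rep(object$pairs$pair_class,
                                each = nrow(object$z)),
               z = as.vector(object$z)) |>
    group_by(.data$window, .data$pair_class) |>
    summarise(eisc = z_mean_r(.data$z), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$eisc,
                                   colour = .data$pair_class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "2 s window", y = "mean eISC") +
    ggplot2::theme_minimal()
}
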