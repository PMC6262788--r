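#' Plots for shape measurements, comet tracks and slices
#'
#' `plot_xz_ratios()` draws the boxplot-with-points figure conventional
#' for x:z ratio comparisons (boxes mark the quartiles and the median).
#'
#' @param measurements shape measurement tibble (from [measure_cells()]),
#'   optionally with a `group` column.
#' @return a ggplot object.
#' @export
plot_xz_ratios <- function(measurements) {
  stopifnot(is.data.frame(measurements), "xz_ratio" %in% names(measurements))
  df <- measurements
  if (!"group" %in% names(df)) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$surface, y = .data$xz_ratio,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "x:z ratio") +
    ggplot2::theme_classic()
}

#' @rdname plot_xz_ratios
#' @param tracks track tibble from [link_tracks()].
#' @export
plot_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "x_um", "y_um") %in% names(tracks)))
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_classic()
}

#' @rdname plot_xz_ratios
#' @param slice an [xz_slice()].
#' @export
plot_slice <- function(slice) {
  stopifnot(inherits(slice, "fs_slice"))
  df <- expand.grid(x = seq_len(nrow(slice$pixels)),
                    z = seq_len(ncol(slice$pixels)))
  df$value <- as.vector(slice$pixels)
  df$x <- px_center(df$x, slice$spacing[1])
  df$z <- px_center(df$z, slice$spacing[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "z (um)",
                  title = sprintf("xz slice at y = %.1f um", slice$y_position)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_xz_ratios
#' @param object object to plot.
#' @param ... unused.
#' @method autoplot fs_slice
#' @export
autoplot.fs_slice <- function(object, ...) plot_slice(object)
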