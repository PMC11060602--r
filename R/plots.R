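#' Plot a line-scan profile with its detected bands
#'
#' @param object A `scan_profile` from [extract_profile()].
#' @param bands Optional band tibble to overlay as shaded intervals.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_profile
#' @export
autoplot.scan_profile <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position_nm, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "position along scan (nm)",
                  y = if (attr(object, "source") == "mask") "mask" else "intensity",
                  title = sprintf("line scan, channel '%s'", attr(object, "channel"))) +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$enter_nm, xmax = .data$exit_nm,
                   ymin = -Inf, ymax = Inf, fill = .data$complete),
      inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                            `FALSE` = "orange"),
                                 name = "complete band")
  }
  p
}

#' Violin plot of leaf measurements by group
#'
#' Mirrors the usual presentation of nested structural measurements:
#' the distribution of all technical measurements per group, with the
#' biological replicate means overlaid as points.
#'
#' @param object A `nested_measures` from [aggregate_measures()].
#' @param measure Which measure to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nested_measures
#' @export
autoplot.nested_measures <- function(object, measure = "length", ...) {
  leaves <- dplyr::filter(object$leaves, .data$measure == !!measure)
  reps <- dplyr::filter(object$by_replicate, .data$measure == !!measure)
  ggplot2::ggplot(leaves, ggplot2::aes(.data$group, .data$value_nm)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_point(data = reps,
                        ggplot2::aes(y = .data$mean_nm),
                        size = 2, colour = "black") +
    ggplot2::labs(x = NULL, y = sprintf("%s (nm)", measure)) +
    ggplot2::theme_minimal()
}

#' Display an image channel as a raster
#'
#' @param object An [image2d()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot image2d
#' @export
autoplot.image2d <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))[(df$col - 1) * nrow(object) + df$row]
  pxsz <- pixel_size(object)
  ggplot2::ggplot(df, ggplot2::aes((.data$col - 0.5) * pxsz / 1000,
                                   (.data$row - 0.5) * pxsz / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("channel '%s'", channel_label(object))) +
    ggplot2::theme_minimal()
}
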