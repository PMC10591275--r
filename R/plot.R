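#' Plot an electrode table
#'
#' Orthogonal 2-D projections of the localized contacts, colored by group.
#' Shifted coordinates, when present, are drawn as open circles connected to
#' their native positions.
#'
#' @param object An electrode table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot electrode_table
#' @export
autoplot.electrode_table <- function(object, ...) {
  tab <- dplyr::filter(tibble::as_tibble(unclass_tbl(object)),
                       !is.na(.data$x))
  long <- dplyr::bind_rows(
    dplyr::transmute(tab, view = "axial (x-y)", h = .data$x, v = .data$y,
                     group = .data$group),
    dplyr::transmute(tab, view = "coronal (x-z)", h = .data$x, v = .data$z,
                     group = .data$group),
    dplyr::transmute(tab, view = "sagittal (y-z)", h = .data$y, v = .data$z,
                     group = .data$group)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v,
                                          colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", colour = "group") +
    ggplot2::theme_minimal()
  if ("x_shifted" %in% names(tab) && any(!is.na(tab$x_shifted))) {
    sh <- dplyr::filter(tab, !is.na(.data$x_shifted))
    shl <- dplyr::bind_rows(
      dplyr::transmute(sh, view = "axial (x-y)", h = .data$x_shifted,
                       v = .data$y_shifted, group = .data$group),
      dplyr::transmute(sh, view = "coronal (x-z)", h = .data$x_shifted,
                       v = .data$z_shifted, group = .data$group),
      dplyr::transmute(sh, view = "sagittal (y-z)", h = .data$y_shifted,
                       v = .data$z_shifted, group = .data$group)
    )
    p <- p + ggplot2::geom_point(data = shl, shape = 1, size = 3)
  }
  p
}

#' Plot detected CT density candidates
#'
#' @param candidates Tibble from [detect_clusters()].
#' @param ... Unused.
#' @return A ggplot object: axial projection, point size by voxel count,
#'   color by peak intensity.
#' @export
plot_candidates <- function(candidates, ...) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(.data$x, .data$y,
                               size = .data$n_voxels,
                               colour = .data$peak_intensity)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", size = "voxels",
                  colour = "peak") +
    ggplot2::theme_minimal()
}
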