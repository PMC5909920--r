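#' Overlay plot of a pipeline run
#'
#' Draws the detected ridge lines, the raw projected centroids (red), the
#' corrected stem positions (blue) and any weed-flagged objects (crosses) in
#' the ground-metric frame, with the y axis pointing down as in the image.
#' Optionally renders the source image behind the overlay.
#'
#' @param object A `spacing_run`.
#' @param image Optional RGB array to draw underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacing_run <- function(object, image = NULL, ...) {
  cam <- object$config$camera
  plants <- object$plants
  weed <- if ("weed" %in% names(plants)) plants$weed else
    rep(FALSE, nrow(plants))
  u <- row_direction(object$ridges$angle_rad[1])
  half <- cam$l_diagonal_m
  segs <- dplyr::mutate(
    tibble::as_tibble(object$ridges),
    x0 = .data$anchor_x_m - half * u[1], y0 = .data$anchor_y_m - half * u[2],
    x1 = .data$anchor_x_m + half * u[1], y1 = .data$anchor_y_m + half * u[2]
  )
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    p <- p + ggplot2::annotation_raster(
      image, xmin = 0, xmax = cam$l_width_m,
      ymin = -cam$l_height_m, ymax = 0
    )
  }
  pts <- dplyr::bind_rows(
    tibble::tibble(x = plants$bx_m[!weed], y = plants$by_m[!weed],
                   what = "projected centroid (B)"),
    tibble::tibble(x = plants$ax_m[!weed], y = plants$ay_m[!weed],
                   what = "corrected stem (A)"),
    tibble::tibble(x = plants$ax_m[weed], y = plants$ay_m[weed],
                   what = "weed (removed)")
  )
  p +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, y = -.data$y0,
                   xend = .data$x1, yend = -.data$y1),
      color = "grey60", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(.data$x, -.data$y, color = .data$what,
                   shape = .data$what),
      size = 1.6
    ) +
    ggplot2::scale_color_manual(
      values = c("projected centroid (B)" = "red",
                 "corrected stem (A)" = "blue",
                 "weed (removed)" = "orange")
    ) +
    ggplot2::scale_shape_manual(
      values = c("projected centroid (B)" = 16,
                 "corrected stem (A)" = 16,
                 "weed (removed)" = 4)
    ) +
    ggplot2::coord_fixed(
      xlim = c(0, cam$l_width_m), ylim = c(-cam$l_height_m, 0), expand = FALSE
    ) +
    ggplot2::labs(x = "x (m)", y = "y (m, down-image)", color = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its ground truth
#'
#' @param object A `plant_scene` from [render_scene()].
#' @param truth Draw true stems and row lines on top? (default `TRUE`)
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plant_scene <- function(object, truth = TRUE, ...) {
  cam <- object$cam
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(
      object$image, xmin = 0, xmax = cam$l_width_m,
      ymin = -cam$l_height_m, ymax = 0
    )
  if (truth) {
    p <- p + ggplot2::geom_point(
      data = object$truth$stems,
      ggplot2::aes(.data$x_m, -.data$y_m),
      color = "blue", shape = 3, size = 1
    )
    if (nrow(object$truth$weeds)) {
      p <- p + ggplot2::geom_point(
        data = object$truth$weeds,
        ggplot2::aes(.data$x_m, -.data$y_m),
        color = "orange", shape = 4, size = 1
      )
    }
  }
  p + ggplot2::coord_fixed(
    xlim = c(0, cam$l_width_m), ylim = c(-cam$l_height_m, 0), expand = FALSE
  ) +
    ggplot2::labs(x = "x (m)", y = "y (m, down-image)") +
    ggplot2::theme_minimal()
}
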