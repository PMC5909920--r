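#' Nadir camera model
#'
#' Describes a camera pointing straight down (nadir) at height `height_m`
#' above flat ground, with a diagonal angle of view `aov_deg` and a sensor of
#' `width_px` by `height_px` pixels. The model owns the linear mapping between
#' image pixel coordinates and ground-metric coordinates: the image diagonal
#' covers a ground length of `2 * tan(aov/2) * height`, split between width
#' and height according to the pixel aspect ratio.
#'
#' Pixel coordinates are continuous, with the origin at the top-left image
#' corner: `x` is the column coordinate (increasing right), `y` the row
#' coordinate (increasing down). The nadir point — the ground point directly
#' under the camera — projects to the image centre `(width_px/2, height_px/2)`.
#'
#' @param height_m Camera height above ground in meters (> 0).
#' @param aov_deg Diagonal angle of view in degrees (0 < aov < 180).
#' @param width_px,height_px Image width and height in pixels (integers > 0).
#'
#' @return An object of class `camera_model`: a list with the inputs plus the
#'   derived ground extents `l_diagonal_m`, `l_width_m`, `l_height_m` and the
#'   ground sampling distance `gsd_m` (meters per pixel).
#' @examples
#' cam <- camera_model(height_m = 2, aov_deg = 72, width_px = 960, height_px = 720)
#' ground_extent(cam)
#' @export
camera_model <- function(height_m, aov_deg, width_px, height_px) {
  if (!is.numeric(height_m) || length(height_m) != 1L || !is.finite(height_m) ||
      height_m <= 0) {
    stop("invalid camera: `height_m` must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(aov_deg) || length(aov_deg) != 1L || !is.finite(aov_deg) ||
      aov_deg <= 0 || aov_deg >= 180) {
    stop("invalid camera: `aov_deg` must lie strictly between 0 and 180",
         call. = FALSE)
  }
  for (d in c(width_px, height_px)) {
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 ||
        d != round(d)) {
      stop("invalid camera: pixel dimensions must be positive integers",
           call. = FALSE)
    }
  }
  v <- aov_deg * pi / 180
  l_diag <- 2 * tan(v / 2) * height_m
  # split the diagonal extent by the pixel aspect ratio
  asp <- atan2(height_px, width_px)
  l_w <- l_diag * cos(asp)
  l_h <- l_diag * sin(asp)
  structure(
    list(
      height_m = height_m,
      aov_deg = aov_deg,
      aov_rad = v,
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      l_diagonal_m = l_diag,
      l_width_m = l_w,
      l_height_m = l_h,
      gsd_m = l_w / width_px
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> H = %.3g m, AOV = %.4g deg (diagonal), %d x %d px\n",
    x$height_m, x$aov_deg, x$width_px, x$height_px
  ))
  cat(sprintf(
    "  ground footprint: %.4g x %.4g m (diagonal %.4g m), GSD %.3g mm/px\n",
    x$l_width_m, x$l_height_m, x$l_diagonal_m, x$gsd_m * 1000
  ))
  invisible(x)
}

#' Ground footprint of a nadir camera
#'
#' The ground lengths covered by the image diagonal, width and height, in
#' meters. The diagonal extent is `2 * tan(v/2) * H` for diagonal angle of
#' view `v` and camera height `H`; width and height follow from the pixel
#' aspect ratio, so `width^2 + height^2 = diagonal^2`.
#'
#' @param cam A [camera_model()].
#' @return A named numeric vector with elements `diagonal`, `width`, `height`
#'   (meters).
#' @export
ground_extent <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  c(diagonal = cam$l_diagonal_m, width = cam$l_width_m, height = cam$l_height_m)
}

#' Ground sampling distance
#'
#' Ground length covered by one pixel (meters per pixel). For a nadir camera
#' with a square-pixel sensor this is identical along x and y.
#'
#' @param cam A [camera_model()].
#' @return A single number, meters per pixel.
#' @export
ground_sampling_distance <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  cam$gsd_m
}

#' Ground-metric coordinates of the nadir point
#'
#' @param cam A [camera_model()].
#' @return Named numeric vector `c(x_m, y_m)`, the image-centre ground point
#'   in the top-left metric frame.
#' @export
nadir_point <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  c(x_m = cam$l_width_m / 2, y_m = cam$l_height_m / 2)
}

#' Convert pixel coordinates to ground-metric coordinates
#'
#' Applies the corner-origin linear map `x_m = x * L_width / NS`,
#' `y_m = y * L_height / NL`. Fractional pixel coordinates are allowed;
#' the top-left corner maps to the metric origin and the image centre maps to
#' the nadir point.
#'
#' @param data A data frame with pixel-coordinate columns.
#' @param cam A [camera_model()].
#' @param x,y Names of the pixel coordinate columns (default `"x"`, `"y"`).
#' @param clamp If `FALSE` (default), out-of-frame pixels raise an error.
#'   If `TRUE`, coordinates are clamped to the frame with a warning — useful
#'   for plants truncated at image borders.
#' @return `data` as a tibble with added columns `x_m`, `y_m` (meters).
#' @examples
#' cam <- camera_model(2, 72, 1000, 1000)
#' pixel_to_metric(data.frame(x = c(0, 500, 1000), y = c(0, 500, 1000)), cam)
#' @export
pixel_to_metric <- function(data, cam, x = "x", y = "y", clamp = FALSE) {
  stopifnot(is.data.frame(data), inherits(cam, "camera_model"))
  px <- data[[x]]
  py <- data[[y]]
  if (is.null(px) || is.null(py)) {
    stop("pixel coordinate columns `", x, "`, `", y, "` not found",
         call. = FALSE)
  }
  oob <- px < 0 | px > cam$width_px | py < 0 | py > cam$height_px
  if (any(oob, na.rm = TRUE)) {
    if (clamp) {
      warning(sum(oob, na.rm = TRUE),
              " pixel coordinate(s) outside the frame were clamped")
      px <- pmin(pmax(px, 0), cam$width_px)
      py <- pmin(pmax(py, 0), cam$height_px)
    } else {
      stop("pixel coordinates outside the image frame; ",
           "use `clamp = TRUE` to clamp truncated points", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(data)
  out$x_m <- px * cam$l_width_m / cam$width_px
  out$y_m <- py * cam$l_height_m / cam$height_px
  out
}

#' Convert ground-metric coordinates to pixel coordinates
#'
#' Inverse of [pixel_to_metric()].
#'
#' @inheritParams pixel_to_metric
#' @param x_m,y_m Names of the metric coordinate columns.
#' @return `data` as a tibble with added columns `x`, `y` (continuous pixels).
#' @export
metric_to_pixel <- function(data, cam, x_m = "x_m", y_m = "y_m") {
  stopifnot(is.data.frame(data), inherits(cam, "camera_model"))
  out <- tibble::as_tibble(data)
  out$x <- out[[x_m]] * cam$width_px / cam$l_width_m
  out$y <- out[[y_m]] * cam$height_px / cam$l_height_m
  out
}

#' Planar Euclidean distance between ground points
#'
#' @param x1,y1,x2,y2 Coordinates in meters (vectorized).
#' @return Distances in meters.
#' @examples
#' metric_distance(0, 0, 3, 4) # 5
#' @export
metric_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}
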