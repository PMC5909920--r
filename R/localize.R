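#' Correct projected centroids to ground stem positions
#'
#' A plant of height `AD` seen off-nadir leans radially outward in the image:
#' its projected-canopy centroid `B` sits beyond its true stem position `A`.
#' Under the model that the projected centroid bisects the stem-to-top ground
#' projection (`AC = 2 AB`), similar triangles give the displacement
#' magnitude
#'
#'   `AB = AD * OB / (2 H - AD)`
#'
#' where `O` is the nadir point, `OB` the centroid's distance from it, and
#' `H` the camera height. The stem position is recovered by moving `B`
#' radially inward toward `O` by `AB`:
#' `A = B - AB * (cos theta, sin theta)` with `theta = atan2(By - Oy, Bx - Ox)`.
#' The correction grows with distance from nadir and with plant height, and
#' vanishes as `H` grows — low flights need the largest correction.
#'
#' @param bx_m,by_m Projected centroid coordinates in the top-left metric
#'   frame (meters, vectorized).
#' @param plant_height_m Uniform plant height `AD` in meters
#'   (`0 <= AD < 2 H`). A single scalar for the whole scene: the crop is
#'   assumed to grow uniformly.
#' @param cam A [camera_model()].
#' @return A tibble with columns `bx_m`, `by_m`, `ax_m`, `ay_m` (corrected
#'   stem position), `ab_m` (displacement magnitude), `theta_rad` (polar angle
#'   of `B` about nadir).
#' @examples
#' cam <- camera_model(1, 72, 1000, 750)
#' # a plant 0.5 m from nadir, 10 cm tall: AB = 0.1 * 0.5 / 1.9
#' correct_centroid(nadir_point(cam)[1] + 0.5, nadir_point(cam)[2], 0.10, cam)
#' @export
correct_centroid <- function(bx_m, by_m, plant_height_m, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (!is.numeric(plant_height_m) || length(plant_height_m) != 1L ||
      plant_height_m < 0) {
    stop("`plant_height_m` must be a single non-negative number",
         call. = FALSE)
  }
  if (plant_height_m >= 2 * cam$height_m) {
    stop("geometry violation: plant height must be below twice the ",
         "camera height (denominator 2H - AD must stay positive)",
         call. = FALSE)
  }
  o <- nadir_point(cam)
  dx <- bx_m - o[["x_m"]]
  dy <- by_m - o[["y_m"]]
  ob <- sqrt(dx^2 + dy^2)
  ab <- plant_height_m * ob / (2 * cam$height_m - plant_height_m)
  theta <- atan2(dy, dx)
  at_nadir <- ob == 0
  theta[at_nadir] <- 0
  tibble::tibble(
    bx_m = bx_m,
    by_m = by_m,
    ax_m = bx_m - ab * cos(theta),
    ay_m = by_m - ab * sin(theta),
    ab_m = ab,
    theta_rad = theta
  )
}

#' Correct all segmented objects to stem positions
#'
#' Converts each object's pixel centroid to the ground-metric frame and
#' applies [correct_centroid()] with a single uniform plant height.
#' Order-preserving.
#'
#' @param objects A `plant_objects` tibble (from [extract_objects()] and
#'   friends) with `centroid_x_px`, `centroid_y_px` columns.
#' @param plant_height_m Uniform plant height in meters.
#' @param cam A [camera_model()].
#' @return A tibble of corrected plants: `object_id`, `bx_m`, `by_m`
#'   (projected centroid), `ax_m`, `ay_m` (stem position), `ab_m`,
#'   `theta_rad`, plus `area_px` and `truncated` carried through when present.
#' @export
correct_plants <- function(objects, plant_height_m, cam) {
  stopifnot(is.data.frame(objects))
  if (nrow(objects) == 0L) {
    return(tibble::tibble(
      object_id = integer(), bx_m = double(), by_m = double(),
      ax_m = double(), ay_m = double(), ab_m = double(), theta_rad = double()
    ))
  }
  met <- pixel_to_metric(objects, cam,
                         x = "centroid_x_px", y = "centroid_y_px")
  out <- correct_centroid(met$x_m, met$y_m, plant_height_m, cam)
  out <- tibble::add_column(out, object_id = objects$object_id, .before = 1)
  for (extra in c("area_px", "truncated")) {
    if (extra %in% names(objects)) out[[extra]] <- objects[[extra]]
  }
  out
}
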