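# Shared fixtures: tiny cameras, masks built from coordinates, small scenes.

toy_cam <- function(height_m = 2, aov_deg = 90, width_px = 1000,
                    height_px = 1000) {
  camera_model(height_m, aov_deg, width_px, height_px)
}

# logical mask from a matrix of (row, col) 1-based pixel indices
mask_from_px <- function(px, nrow = 20, ncol = 20) {
  m <- matrix(FALSE, nrow, ncol)
  m[as.matrix(px)] <- TRUE
  m
}

# a bare plant_objects-like tibble for filter tests (no label matrix needed)
fake_objects <- function(area, shape = rep(1, length(area))) {
  tibble::tibble(
    object_id = seq_along(area),
    area_px = area,
    perimeter_px = shape * area,
    shape_ratio = shape,
    centroid_x_px = seq_along(area),
    centroid_y_px = seq_along(area),
    truncated = FALSE
  )
}

# corrected-plant tibble straight from coordinates
plants_at <- function(x, y, ids = seq_along(x)) {
  tibble::tibble(object_id = ids, ax_m = x, ay_m = y)
}

# small, fast indoor scene (reduced sensor keeps unit tests snappy)
small_indoor_scene <- function(seed = 1, interval_m = 0.18, height_m = 2,
                               ...) {
  render_scene(indoor_scene_spec(
    interval_m = interval_m, height_m = height_m, seed = seed,
    width_px = 480, height_px = 360, ...
  ))
}

# default pipeline config for a rendered scene
scene_config <- function(scene, threshold_mode = "fixed",
                         fixed_threshold = 0, ...) {
  run_config(
    camera = scene$cam,
    plant_height_m = scene$spec$plant_height_m,
    row_angle_deg = scene$spec$row_angle_deg,
    row_width_m = scene$spec$row_width_m,
    threshold_mode = threshold_mode,
    fixed_threshold = fixed_threshold,
    ...
  )
}
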