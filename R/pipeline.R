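#' Read an RGB image from disk
#'
#' Supports PNG and TIFF (8/16-bit, values returned on `[0, 1]`).
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric array `[rows, cols, 3]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format `.", ext, "` (PNG and TIFF are supported)",
         call. = FALSE)
  )
  if (length(dim(img)) == 2L) stop("single-channel image: RGB required",
                                   call. = FALSE)
  img[, , 1:3, drop = FALSE]
}

#' Pipeline run configuration
#'
#' Collects every tunable of the spacing pipeline in one validated object.
#' Defaults follow the standard parameterization for early-stage maize:
#' area/shape filter thresholds 0.3/0.3, row-membership buffer of one third
#' of the row width, a 4 cm fragment-merge radius, and weed tolerance equal
#' to the membership buffer.
#'
#' @param camera A [camera_model()] or a list with `height_m`, `aov_deg`,
#'   `width_px`, `height_px`.
#' @param plant_height_m Uniform plant height (m).
#' @param row_angle_deg,row_width_m Row prior knowledge (see
#'   [detect_ridges()]).
#' @param threshold_mode `"otsu"` or `"fixed"`. @param fixed_threshold EXG
#'   cutoff for `"fixed"` mode (e.g. 0 indoors, 0.1 in the field).
#' @param exg_normalize Band normalization for [compute_exg()].
#' @param t_area,t_shape,shape_keep Object filter settings
#'   ([filter_objects()]).
#' @param dilation_radius_m Fragment-merge dilation radius in ground meters
#'   (converted to pixels through the camera's GSD; 0 disables merging).
#' @param buffer_frac Row membership buffer fraction (default 1/3).
#' @param weed_filter Apply the ridge-buffer weed filter? (default `FALSE`;
#'   enable for field scenes).
#' @param weed_tolerance_m Weed distance tolerance; `NULL` = the membership
#'   buffer `buffer_frac * row_width_m`.
#' @param min_members,member_frac Ridge pruning before weed filtering
#'   ([prune_ridges()]; only used when `weed_filter = TRUE`).
#' @param refine_iters,seed_method Ridge detection settings
#'   ([detect_ridges()]).
#' @return A list of class `run_config` with a stable `hash` field for
#'   provenance.
#' @export
run_config <- function(camera, plant_height_m,
                       row_angle_deg = 90, row_width_m = 0.765,
                       threshold_mode = c("otsu", "fixed"),
                       fixed_threshold = 0,
                       exg_normalize = c("image", "depth"),
                       t_area = 0.3, t_shape = 0.3,
                       shape_keep = c("above", "below"),
                       dilation_radius_m = 0.04,
                       buffer_frac = 1 / 3,
                       weed_filter = FALSE, weed_tolerance_m = NULL,
                       min_members = 2, member_frac = 0.3,
                       refine_iters = 1,
                       seed_method = c("center", "random")) {
  if (!inherits(camera, "camera_model")) {
    if (!is.list(camera) ||
        !all(c("height_m", "aov_deg", "width_px", "height_px") %in%
             names(camera))) {
      stop("config schema error: `camera` needs height_m, aov_deg, ",
           "width_px, height_px", call. = FALSE)
    }
    camera <- camera_model(camera$height_m, camera$aov_deg,
                           camera$width_px, camera$height_px)
  }
  stopifnot(is.numeric(plant_height_m), plant_height_m >= 0,
            row_width_m > 0, dilation_radius_m >= 0)
  cfg <- list(
    camera = camera,
    plant_height_m = plant_height_m,
    row_angle_deg = row_angle_deg,
    row_width_m = row_width_m,
    threshold_mode = match.arg(threshold_mode),
    fixed_threshold = fixed_threshold,
    exg_normalize = match.arg(exg_normalize),
    t_area = t_area, t_shape = t_shape,
    shape_keep = match.arg(shape_keep),
    dilation_radius_m = dilation_radius_m,
    buffer_frac = buffer_frac,
    weed_filter = isTRUE(weed_filter),
    weed_tolerance_m = weed_tolerance_m %||% buffer_frac * row_width_m,
    min_members = min_members, member_frac = member_frac,
    refine_iters = refine_iters,
    seed_method = match.arg(seed_method)
  )
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Run the full plant-spacing pipeline on one image
#'
#' Segmentation (EXG, threshold, component extraction, outlier filtering,
#' fragment merging) followed by perspective centroid correction, ridge
#' detection, optional weed filtering, projection onto ridges and interval
#' measurement.
#'
#' @param image An RGB array `[rows, cols, 3]` or a PNG/TIFF file path.
#' @param config A [run_config()]. Its camera pixel dimensions must match
#'   the image.
#' @return An object of class `spacing_run`: a list with tibbles `objects`
#'   (segmented objects), `plants` (corrected stem positions, plus weed flags
#'   when filtering), `ridges`, `spacing` (interval table), the `config`, the
#'   EXG `threshold` used, and a `warnings` character vector of data-quality
#'   notes (truncated plants, duplicate intervals, weed removals). Use
#'   [generics::tidy()] for the interval table, [generics::glance()] for a
#'   one-row summary, and [ggplot2::autoplot()] for an overlay figure.
#' @export
run_pipeline <- function(image, config) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(image)) image <- read_image(image)
  cam <- config$camera
  if (!all(dim(image)[1:2] == c(cam$height_px, cam$width_px))) {
    stop("image dimensions do not match the configured camera",
         call. = FALSE)
  }
  notes <- character()
  note <- function(...) notes <<- c(notes, sprintf(...))

  exg <- compute_exg(image, normalize = config$exg_normalize)
  mask <- threshold_vegetation(
    exg, mode = config$threshold_mode,
    fixed_value = config$fixed_threshold
  )
  objects <- extract_objects(mask)
  if (nrow(objects) == 0L) {
    stop("zero plants detected: no vegetation above the threshold",
         call. = FALSE)
  }
  objects <- filter_objects(objects, t_area = config$t_area,
                            t_shape = config$t_shape,
                            shape_keep = config$shape_keep)
  if (config$dilation_radius_m > 0) {
    radius_px <- config$dilation_radius_m / cam$gsd_m
    objects <- merge_fragments(objects, radius_px)
  }
  if (nrow(objects) == 0L) {
    stop("zero plants detected: all objects removed by filtering",
         call. = FALSE)
  }
  if (any(objects$truncated)) {
    note("%d object(s) truncated at the image border",
         sum(objects$truncated))
  }

  plants <- correct_plants(objects, config$plant_height_m, cam)
  ridges <- detect_ridges(
    plants, angle_deg = config$row_angle_deg,
    row_width_m = config$row_width_m, buffer_frac = config$buffer_frac,
    seed_method = config$seed_method,
    center = nadir_point(cam), refine_iters = config$refine_iters
  )
  if (config$weed_filter) {
    ridges <- prune_ridges(ridges, min_members = config$min_members,
                           member_frac = config$member_frac)
    plants <- filter_weeds(plants, ridges,
                           tolerance_m = config$weed_tolerance_m)
    if (any(plants$weed)) {
      note("%d object(s) beyond %.3g m of every ridge flagged as weeds",
           sum(plants$weed), config$weed_tolerance_m)
    }
  }
  projected <- project_to_ridges(plants, ridges)
  spacing <- withCallingHandlers(
    measure_spacing(projected, ridges, cam = cam),
    warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  structure(
    list(
      objects = objects,
      plants = plants,
      projected = projected,
      ridges = ridges,
      spacing = spacing,
      config = config,
      threshold = attr(mask, "threshold"),
      warnings = notes
    ),
    class = "spacing_run"
  )
}

#' @export
print.spacing_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<spacing_run> %d objects -> %d plants on %d ridges; %d intervals, mean %.3f m (sd %.3f)\n",
    g$n_objects, g$n_plants, g$n_ridges, g$n_intervals,
    g$mean_interval_m, g$sd_interval_m
  ))
  for (w in x$warnings) cat(" note:", w, "\n")
  invisible(x)
}
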