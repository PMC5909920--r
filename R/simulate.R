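#' Specify a synthetic row-planted scene
#'
#' Bundles every parameter of the forward scene model: the nadir camera, the
#' planting pattern (row angle, row width, within-row interval), plant
#' geometry (height, leaf size/number/asymmetry), background (soil color,
#' pixel noise), and contamination (weed and residue densities). The defaults
#' describe a maize stand shortly after emergence (around V2, two expanded
#' leaves) photographed with a 72-degree diagonal-AOV camera.
#'
#' Plants are rendered as glyphs of `leaf_count` elliptical lobes around a
#' stem point, at seeded-random orientations, with opposite leaves paired the
#' way V2 maize leaves emerge. `leaf_asym` draws a relative length imbalance
#' between the two leaves of a pair, displacing the canopy centroid off the
#' stem — the leaf-architecture noise that limits centroid-based stem
#' location in real imagery. The canopy centroid of each glyph is displaced
#' radially OUTWARD from nadir by exactly `AB = AD * OB / (2H - AD)` (the
#' forward counterpart of the correction in [correct_centroid()]), and glyphs
#' are elongated radially by the same projection factor.
#'
#' @param height_m Camera height (m). @param aov_deg Diagonal AOV (degrees).
#' @param width_px,height_px Sensor size in pixels.
#' @param row_angle_deg Row angle, degrees CCW from +x (default 90:
#'   vertical rows).
#' @param row_width_m Distance between adjacent rows (m).
#' @param interval_m Nominal within-row plant interval (m).
#' @param plant_height_m Uniform plant height `AD` (m, must stay below
#'   `height_m`).
#' @param leaf_length_m,leaf_width_m Single-leaf length and width (m).
#' @param leaf_count Number of leaf lobes per plant (default 2: one pair).
#' @param leaf_asym Upper bound of the uniform relative length imbalance
#'   between opposite leaves (default 0.25; 0 = perfectly symmetric glyphs).
#' @param spacing_jitter_sd_m SD of Gaussian jitter on successive intervals
#'   (m). @param lateral_jitter_sd_m SD of stem scatter across the row line
#'   (m).
#' @param weed_density Weeds per square meter, placed in the inter-row lanes.
#' @param weed_height_m Weed canopy height (m), used for their own radial
#'   displacement. @param weed_lane_jitter_m Half-width of the uniform weed
#'   scatter about the lane centerline (m).
#' @param residue_density Pale residue streaks per square meter.
#' @param soil_rgb,plant_rgb,weed_rgb,residue_rgb Mean RGB triplets on
#'   `[0, 1]`. Defaults put soil EXG around -0.19, residue around +0.03 and
#'   vegetation above 0.9, so both the Otsu and fixed-threshold paths are
#'   exercisable.
#' @param noise_sd SD of Gaussian per-pixel channel noise (0 = noise-free).
#' @param margin_m Keep-out border for stem placement; `NULL` (default)
#'   derives it from leaf reach plus the worst-case radial displacement so no
#'   glyph is truncated at the image border.
#' @param seed Integer RNG seed; every random choice in the renderer flows
#'   from it.
#' @return A list of class `scene_spec`.
#' @seealso [render_scene()], [indoor_scene_spec()], [field_scene_spec()]
#' @export
scene_spec <- function(height_m = 2, aov_deg = 72,
                       width_px = 960, height_px = 720,
                       row_angle_deg = 90, row_width_m = 0.765,
                       interval_m = 0.18, plant_height_m = 0.10,
                       leaf_length_m = 0.04, leaf_width_m = 0.015,
                       leaf_count = 2, leaf_asym = 0.25,
                       spacing_jitter_sd_m = 0.01,
                       lateral_jitter_sd_m = 0.005,
                       weed_density = 0, weed_height_m = 0.08,
                       weed_lane_jitter_m = 0.06,
                       residue_density = 0,
                       soil_rgb = c(0.50, 0.28, 0.26),
                       plant_rgb = c(0.15, 0.55, 0.12),
                       weed_rgb = c(0.20, 0.50, 0.15),
                       residue_rgb = c(0.55, 0.50, 0.40),
                       noise_sd = 0.02,
                       margin_m = NULL, seed = 1) {
  stopifnot(row_width_m > 0, interval_m > 0, plant_height_m >= 0,
            leaf_length_m > 0, leaf_width_m > 0, leaf_count >= 1,
            leaf_asym >= 0, leaf_asym < 1,
            weed_density >= 0, residue_density >= 0, noise_sd >= 0)
  if (plant_height_m >= height_m) {
    stop("forward model requires plant height below camera height",
         call. = FALSE)
  }
  spec <- list(
    height_m = height_m, aov_deg = aov_deg,
    width_px = width_px, height_px = height_px,
    row_angle_deg = row_angle_deg, row_width_m = row_width_m,
    interval_m = interval_m, plant_height_m = plant_height_m,
    leaf_length_m = leaf_length_m, leaf_width_m = leaf_width_m,
    leaf_count = leaf_count, leaf_asym = leaf_asym,
    spacing_jitter_sd_m = spacing_jitter_sd_m,
    lateral_jitter_sd_m = lateral_jitter_sd_m,
    weed_density = weed_density, weed_height_m = weed_height_m,
    weed_lane_jitter_m = weed_lane_jitter_m,
    residue_density = residue_density,
    soil_rgb = soil_rgb, plant_rgb = plant_rgb,
    weed_rgb = weed_rgb, residue_rgb = residue_rgb,
    noise_sd = noise_sd, margin_m = margin_m, seed = as.integer(seed)
  )
  structure(spec, class = "scene_spec")
}

#' Preset: indoor artificial-plant scene
#'
#' Emulates the controlled indoor stand: bare soil, no weeds or residue,
#' 76.5 cm rows, 10 cm plants, intervals chosen from the tested design
#' spacings (9/18/27/36 cm).
#'
#' @param interval_m Within-row interval (m). @param height_m Camera height.
#' @param seed RNG seed. @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
indoor_scene_spec <- function(interval_m = 0.18, height_m = 2, seed = 1, ...) {
  args <- list(
    height_m = height_m, interval_m = interval_m,
    row_width_m = 0.765, plant_height_m = 0.10,
    weed_density = 0, residue_density = 0,
    spacing_jitter_sd_m = 0.01, lateral_jitter_sd_m = 0.005,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

#' Preset: field scene with weeds and residue
#'
#' Emulates a high-density commercial planting: 53 cm rows, ~20 cm
#' intervals, 15 cm plants, weeds scattered between the rows and pale
#' residue streaks on the soil.
#'
#' @param height_m Camera height (m). @param seed RNG seed.
#' @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
field_scene_spec <- function(height_m = 3, seed = 1, ...) {
  args <- list(
    height_m = height_m, interval_m = 0.20,
    row_width_m = 0.53, plant_height_m = 0.15,
    weed_density = 0.5, residue_density = 0.3,
    spacing_jitter_sd_m = 0.02, lateral_jitter_sd_m = 0.01,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

# Clip the line anchor + t*u to the axis-aligned rectangle
# [xmin,xmax] x [ymin,ymax]; returns c(t0, t1) or NULL if no overlap.
clip_line_to_rect <- function(anchor, u, xmin, xmax, ymin, ymax) {
  t0 <- -Inf; t1 <- Inf
  for (dim in 1:2) {
    lo <- if (dim == 1) xmin else ymin
    hi <- if (dim == 1) xmax else ymax
    if (abs(u[dim]) < 1e-12) {
      if (anchor[dim] < lo || anchor[dim] > hi) return(NULL)
    } else {
      ta <- (lo - anchor[dim]) / u[dim]
      tb <- (hi - anchor[dim]) / u[dim]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(NULL)
  c(t0, t1)
}

# Rasterize a glyph of elliptical lobes. `ellipses` is a data frame with
# absolute lobe centers (cx, cy), semi-axes (a along phi, b across), and
# orientation phi. The glyph is elongated by factor `f` along the radial
# unit vector `e_r` about `center` (inverse transform applied to pixel
# coordinates). Returns an index matrix cbind(row, col) of covered pixels.
glyph_pixels <- function(cam, center, ellipses, f = 1, e_r = c(1, 0)) {
  gx <- cam$l_width_m / cam$width_px
  gy <- cam$l_height_m / cam$height_px
  reach <- max(sqrt((ellipses$cx - center[1])^2 +
                    (ellipses$cy - center[2])^2) + ellipses$a) *
    max(f, 1) + max(ellipses$b)
  j0 <- max(1L, as.integer(floor((center[1] - reach) / gx)))
  j1 <- min(cam$width_px, as.integer(ceiling((center[1] + reach) / gx)))
  i0 <- max(1L, as.integer(floor((center[2] - reach) / gy)))
  i1 <- min(cam$height_px, as.integer(ceiling((center[2] + reach) / gy)))
  if (j0 > j1 || i0 > i1) return(cbind(row = integer(), col = integer()))
  jj <- j0:j1; ii <- i0:i1
  px <- (rep(jj, each = length(ii)) - 0.5) * gx
  py <- (rep(ii, times = length(jj)) - 0.5) * gy
  dx <- px - center[1]; dy <- py - center[2]
  if (f != 1) {
    pr <- (dx * e_r[1] + dy * e_r[2]) / f
    pt <- -dx * e_r[2] + dy * e_r[1]
    dx <- pr * e_r[1] - pt * e_r[2]
    dy <- pr * e_r[2] + pt * e_r[1]
  }
  qx <- center[1] + dx; qy <- center[2] + dy
  inside <- rep(FALSE, length(qx))
  for (k in seq_len(nrow(ellipses))) {
    ex <- qx - ellipses$cx[k]; ey <- qy - ellipses$cy[k]
    ca <- cos(ellipses$phi[k]); sa <- sin(ellipses$phi[k])
    lon <- ex * ca + ey * sa
    lat <- -ex * sa + ey * ca
    inside <- inside |
      (lon / ellipses$a[k])^2 + (lat / ellipses$b[k])^2 <= 1
  }
  cbind(row = rep(ii, times = length(jj))[inside],
        col = rep(jj, each = length(ii))[inside])
}

# Leaf lobes of one plant glyph centered (pre-displacement) at the stem,
# plus a small stem/whorl disk that keeps the lobes connected when the
# leaves are only a few pixels wide.
plant_lobes <- function(center, phi0, lengths, width) {
  k <- length(lengths)
  phis <- phi0 + (seq_len(k) - 1) * 2 * pi / k
  lobes <- tibble::tibble(
    cx = center[1] + lengths / 2 * cos(phis),
    cy = center[2] + lengths / 2 * sin(phis),
    a = lengths / 2,
    b = width / 2,
    phi = phis
  )
  dplyr::bind_rows(
    lobes,
    tibble::tibble(cx = center[1], cy = center[2],
                   a = width / 2, b = width / 2, phi = 0)
  )
}

#' Render a synthetic nadir scene with ground truth
#'
#' Places stems on row lines at the specified interval (plus jitter), renders
#' each plant as a green multi-leaf glyph whose canopy centroid is displaced
#' radially outward from nadir according to the perspective model, adds soil
#' background with channel noise and optional inter-row weeds and residue
#' streaks, and returns the RGB raster together with the full ground truth.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `plant_scene`:
#'   * `image` — numeric array `[height_px, width_px, 3]` on `[0, 1]`;
#'   * `truth` — list with `stems` (stem_id, row_id, true stem `x_m`/`y_m`,
#'     displaced canopy center `bx_m`/`by_m`, along-row coordinate `t_m`),
#'     `rows` (row_id, angle_rad, anchor and signed offset of each true row
#'     line), `intervals` (row_id, rank, true consecutive stem distance
#'     `interval_m`), and `weeds` (weed_id, ground position, radius);
#'   * `spec`, `cam` — the inputs used.
#'
#'   Rendering is fully determined by `spec$seed`: the same spec gives a
#'   byte-identical image and truth.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cam <- camera_model(spec$height_m, spec$aov_deg,
                      spec$width_px, spec$height_px)
  H <- cam$height_m
  AD <- spec$plant_height_m
  f_plant <- (2 * H - AD) / (2 * (H - AD))
  f_weed <- (2 * H - spec$weed_height_m) / (2 * (H - spec$weed_height_m))
  o <- nadir_point(cam)
  angle_rad <- (spec$row_angle_deg %% 180) * pi / 180
  u <- row_direction(angle_rad)
  nv <- row_normal(angle_rad)

  corner_r <- cam$l_diagonal_m / 2
  margin <- spec$margin_m
  if (is.null(margin)) {
    margin <- spec$leaf_length_m * (1 + spec$leaf_asym) * f_plant +
      corner_r * (f_plant - 1) + spec$leaf_width_m + 2 * cam$gsd_m
  }
  xmin <- margin; xmax <- cam$l_width_m - margin
  ymin <- margin; ymax <- cam$l_height_m - margin
  if (xmax - xmin < spec$interval_m && ymax - ymin < spec$interval_m) {
    stop("empty scene: ground footprint too small for one plant interval",
         call. = FALSE)
  }
  center <- c(o[["x_m"]], o[["y_m"]])
  c0 <- signed_offset(center[1], center[2], angle_rad)

  withr::with_seed(spec$seed, {
    # --- stems on row lines -------------------------------------------------
    kmax <- ceiling(cam$l_diagonal_m / spec$row_width_m)
    rows <- list(); stems <- list(); next_row <- 1L
    for (k in -kmax:kmax) {
      offk <- c0 + k * spec$row_width_m
      anchor <- center + (offk - c0) * nv
      tr <- clip_line_to_rect(anchor, u, xmin, xmax, ymin, ymax)
      if (is.null(tr) || diff(tr) < spec$interval_m) next
      t <- tr[1] + stats::runif(1, 0.2, 0.8) * spec$interval_m
      ts <- numeric()
      while (t <= tr[2]) {
        ts <- c(ts, t)
        t <- t + spec$interval_m +
          stats::rnorm(1, 0, spec$spacing_jitter_sd_m)
      }
      if (length(ts) == 0L) next
      lat <- stats::rnorm(length(ts), 0, spec$lateral_jitter_sd_m)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        row_id = next_row, angle_rad = angle_rad,
        anchor_x_m = anchor[1], anchor_y_m = anchor[2], offset_m = offk
      )
      stems[[length(stems) + 1L]] <- tibble::tibble(
        row_id = next_row, t_m = ts,
        x_m = anchor[1] + ts * u[1] + lat * nv[1],
        y_m = anchor[2] + ts * u[2] + lat * nv[2]
      )
      next_row <- next_row + 1L
    }
    if (length(stems) == 0L) {
      stop("empty scene: no row line fits the usable footprint",
           call. = FALSE)
    }
    rows <- dplyr::bind_rows(rows)
    stems <- dplyr::bind_rows(stems)
    stems <- tibble::add_column(stems, stem_id = seq_len(nrow(stems)),
                                .before = 1)

    # forward radial displacement of the canopy centroid
    stems$bx_m <- o[["x_m"]] + (stems$x_m - o[["x_m"]]) * f_plant
    stems$by_m <- o[["y_m"]] + (stems$y_m - o[["y_m"]]) * f_plant

    intervals <- dplyr::mutate(
      dplyr::group_by(stems, .data$row_id),
      interval_m = c(NA_real_,
                     sqrt(diff(.data$x_m)^2 + diff(.data$y_m)^2)),
      rank = dplyr::row_number() - 1L
    )
    intervals <- dplyr::ungroup(intervals)
    intervals <- intervals[!is.na(intervals$interval_m),
                           c("row_id", "rank", "interval_m")]

    # --- weeds in the inter-row lanes --------------------------------------
    weeds <- tibble::tibble(weed_id = integer(), x_m = double(),
                            y_m = double(), radius_m = double())
    if (spec$weed_density > 0 && nrow(rows) >= 2L) {
      lane_offs <- (rows$offset_m[-1] + rows$offset_m[-nrow(rows)]) / 2
      wlist <- list()
      for (loff in lane_offs) {
        anchor <- center + (loff - c0) * nv
        tr <- clip_line_to_rect(anchor, u, xmin, xmax, ymin, ymax)
        if (is.null(tr)) next
        lane_area <- diff(tr) * spec$row_width_m
        nw <- stats::rpois(1, spec$weed_density * lane_area)
        if (nw == 0L) next
        tw <- stats::runif(nw, tr[1], tr[2])
        ow <- loff + stats::runif(nw, -spec$weed_lane_jitter_m,
                                  spec$weed_lane_jitter_m)
        wlist[[length(wlist) + 1L]] <- tibble::tibble(
          x_m = center[1] + tw * u[1] + (ow - c0) * nv[1],
          y_m = center[2] + tw * u[2] + (ow - c0) * nv[2],
          radius_m = stats::runif(nw, 0.012, 0.025)
        )
      }
      if (length(wlist)) {
        weeds <- dplyr::bind_rows(wlist)
        weeds <- tibble::add_column(weeds, weed_id = seq_len(nrow(weeds)),
                                    .before = 1)
      }
    }

    # --- residue streaks ----------------------------------------------------
    n_res <- if (spec$residue_density > 0) {
      stats::rpois(1, spec$residue_density * cam$l_width_m * cam$l_height_m)
    } else 0L
    residue <- if (n_res > 0) {
      tibble::tibble(
        cx = stats::runif(n_res, 0, cam$l_width_m),
        cy = stats::runif(n_res, 0, cam$l_height_m),
        a = stats::runif(n_res, 0.05, 0.15) / 2,
        b = stats::runif(n_res, 0.01, 0.03) / 2,
        phi = stats::runif(n_res, 0, pi)
      )
    } else NULL

    # --- compose the raster -------------------------------------------------
    NL <- cam$height_px; NS <- cam$width_px
    chan <- lapply(spec$soil_rgb, function(v) matrix(v, NL, NS))
    paint <- function(chan, px, rgb) {
      if (nrow(px) == 0L) return(chan)
      for (c3 in 1:3) chan[[c3]][px] <- rgb[c3]
      chan
    }
    if (!is.null(residue)) {
      for (k in seq_len(nrow(residue))) {
        px <- glyph_pixels(cam, c(residue$cx[k], residue$cy[k]),
                           residue[k, , drop = FALSE])
        chan <- paint(chan, px, spec$residue_rgb)
      }
    }
    if (nrow(weeds) > 0) {
      for (k in seq_len(nrow(weeds))) {
        wb <- c(o[["x_m"]] + (weeds$x_m[k] - o[["x_m"]]) * f_weed,
                o[["y_m"]] + (weeds$y_m[k] - o[["y_m"]]) * f_weed)
        ell <- tibble::tibble(cx = wb[1], cy = wb[2],
                              a = weeds$radius_m[k], b = weeds$radius_m[k],
                              phi = 0)
        px <- glyph_pixels(cam, wb, ell)
        chan <- paint(chan, px, spec$weed_rgb)
      }
    }
    for (k in seq_len(nrow(stems))) {
      phi0 <- stats::runif(1, 0, pi)
      delta <- if (spec$leaf_asym > 0) {
        stats::runif(1, 0, spec$leaf_asym)
      } else 0
      lens <- spec$leaf_length_m *
        (1 + delta * rep_len(c(1, -1), spec$leaf_count))
      bc <- c(stems$bx_m[k], stems$by_m[k])
      dr <- bc - center
      e_r <- if (sum(dr^2) > 0) dr / sqrt(sum(dr^2)) else c(1, 0)
      lobes <- plant_lobes(bc, phi0, lens, spec$leaf_width_m)
      px <- glyph_pixels(cam, bc, lobes, f = f_plant, e_r = e_r)
      chan <- paint(chan, px, spec$plant_rgb)
    }
    img <- array(0, dim = c(NL, NS, 3))
    for (c3 in 1:3) img[, , c3] <- chan[[c3]]
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }

    structure(
      list(
        image = img,
        truth = list(stems = stems, rows = rows, intervals = intervals,
                     weeds = weeds),
        spec = spec,
        cam = cam
      ),
      class = "plant_scene"
    )
  })
}

#' @export
print.plant_scene <- function(x, ...) {
  cat(sprintf(
    "<plant_scene> %d x %d px, H = %.3g m; %d stems on %d rows, %d weeds\n",
    x$cam$width_px, x$cam$height_px, x$cam$height_m,
    nrow(x$truth$stems), nrow(x$truth$rows), nrow(x$truth$weeds)
  ))
  invisible(x)
}

#' Scenario grid of scene specifications
#'
#' Builds the Cartesian product of within-row intervals and camera heights,
#' named `S_<x>cm_<y>m` after the interval/height combination, with one
#' deterministic seed per cell derived from `base_seed`. Scenes are rendered
#' on demand with [render_scene()] (twenty full-size rasters need not sit in
#' memory at once).
#'
#' @param intervals_m Numeric vector of within-row intervals (m).
#' @param heights_m Numeric vector of camera heights (m).
#' @param base_seed Integer; cell seeds are `base_seed * 1000 + cell index`.
#' @param spec_fun Function `(interval_m, height_m, seed, ...) -> scene_spec`
#'   used for each cell (default [indoor_scene_spec()]).
#' @param ... Passed on to `spec_fun`.
#' @return A tibble with columns `scenario`, `interval_m`, `height_m`,
#'   `seed`, and a `spec` list-column of [scene_spec()] objects.
#' @examples
#' grid <- scenario_grid(c(0.09, 0.18), heights_m = c(1, 2), base_seed = 7)
#' grid$scenario
#' @export
scenario_grid <- function(intervals_m, heights_m, base_seed = 1,
                          spec_fun = indoor_scene_spec, ...) {
  stopifnot(length(intervals_m) >= 1, length(heights_m) >= 1)
  cells <- tidyr::expand_grid(interval_m = intervals_m, height_m = heights_m)
  cells$scenario <- sprintf("S_%gcm_%gm", cells$interval_m * 100,
                            cells$height_m)
  cells$seed <- as.integer(base_seed * 1000 + seq_len(nrow(cells)))
  cells$spec <- purrr::pmap(
    list(cells$interval_m, cells$height_m, cells$seed),
    function(iv, h, s) spec_fun(interval_m = iv, height_m = h, seed = s, ...)
  )
  cells[, c("scenario", "interval_m", "height_m", "seed", "spec")]
}
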