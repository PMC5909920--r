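test_that("rendering is fully determined by the seed", {
  a <- small_indoor_scene(seed = 5)
  b <- small_indoor_scene(seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- small_indoor_scene(seed = 6)
  expect_false(identical(a$image, c$image))
})

test_that("scene truth is internally consistent", {
  sc <- small_indoor_scene(seed = 9)
  st <- sc$truth$stems
  # recorded intervals equal consecutive stem distances
  for (rid in unique(st$row_id)) {
    s <- st[st$row_id == rid, ]
    expect_equal(
      sc$truth$intervals$interval_m[sc$truth$intervals$row_id == rid],
      sqrt(diff(s$x_m)^2 + diff(s$y_m)^2),
      tolerance = 1e-9
    )
  }
  # stems inside the footprint, rows parallel at the configured angle
  expect_true(all(st$x_m > 0 & st$x_m < sc$cam$l_width_m))
  expect_true(all(st$y_m > 0 & st$y_m < sc$cam$l_height_m))
  expect_equal(unique(sc$truth$rows$angle_rad), pi / 2)
  expect_equal(diff(sort(sc$truth$rows$offset_m)),
               rep(sc$spec$row_width_m, nrow(sc$truth$rows) - 1),
               tolerance = 1e-12)
})

test_that("canopy centroids are displaced radially by the projection factor", {
  sc <- small_indoor_scene(seed = 3)
  o <- nadir_point(sc$cam)
  H <- sc$cam$height_m; AD <- sc$spec$plant_height_m
  f <- (2 * H - AD) / (2 * (H - AD))
  st <- sc$truth$stems
  expect_equal(st$bx_m - o[["x_m"]], (st$x_m - o[["x_m"]]) * f,
               tolerance = 1e-12)
  expect_equal(st$by_m - o[["y_m"]], (st$y_m - o[["y_m"]]) * f,
               tolerance = 1e-12)
  # displacement is outward: B is never closer to nadir than A
  oa <- metric_distance(st$x_m, st$y_m, o[["x_m"]], o[["y_m"]])
  ob <- metric_distance(st$bx_m, st$by_m, o[["x_m"]], o[["y_m"]])
  expect_true(all(ob >= oa))
})

test_that("a clean scene segments into exactly one object per stem", {
  sc <- small_indoor_scene(seed = 12, spacing_jitter_sd_m = 0,
                           weed_density = 0, residue_density = 0)
  exg <- compute_exg(sc$image)
  obj <- filter_objects(extract_objects(threshold_vegetation(exg, "fixed",
                                                             0)))
  expect_equal(nrow(obj), nrow(sc$truth$stems))
})

test_that("field scenes place weeds strictly between the rows", {
  sc <- render_scene(field_scene_spec(height_m = 3, seed = 4,
                                      width_px = 480, height_px = 360))
  expect_gt(nrow(sc$truth$weeds), 0)
  w <- sc$spec$row_width_m
  offs <- sort(sc$truth$rows$offset_m)
  weed_off <- sc$truth$weeds$x_m # vertical rows: signed offset = x
  dmin <- apply(abs(outer(weed_off, offs, "-")), 1, min)
  expect_true(all(dmin > w / 3)) # beyond the membership buffer
  expect_true(all(dmin < w))     # but inside the lanes
})

test_that("the scenario grid is the named, seeded Cartesian product", {
  grid <- scenario_grid(c(0.09, 0.18, 0.27, 0.36), 1:5, base_seed = 2)
  expect_equal(nrow(grid), 20)
  expect_equal(grid$scenario[1], "S_9cm_1m")
  expect_equal(grid$scenario[20], "S_36cm_5m")
  expect_equal(anyDuplicated(grid$seed), 0L)

  single <- scenario_grid(0.18, 2, base_seed = 2)
  expect_equal(nrow(single), 1)

  # identical base seed, identical truths
  g2 <- scenario_grid(c(0.09, 0.18, 0.27, 0.36), 1:5, base_seed = 2)
  expect_identical(grid$spec, g2$spec)
  sc1 <- render_scene(scenario_grid(0.18, 2, base_seed = 3,
                                    width_px = 320, height_px = 240)$spec[[1]])
  sc2 <- render_scene(scenario_grid(0.18, 2, base_seed = 3,
                                    width_px = 320, height_px = 240)$spec[[1]])
  expect_identical(sc1$truth, sc2$truth)
})

test_that("impossible scenes are rejected", {
  expect_error(render_scene(scene_spec(height_m = 0.3, interval_m = 1.5)),
               "empty scene")
  expect_error(scene_spec(height_m = 1, plant_height_m = 1.2),
               "plant height")
})
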