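test_that("ground extents match closed forms", {
  cam <- camera_model(2, 90, 1000, 1000)
  ext <- ground_extent(cam)
  expect_equal(ext[["diagonal"]], 4)
  expect_equal(ext[["width"]], 4 / sqrt(2))
  expect_equal(ext[["height"]], 4 / sqrt(2))

  cam72 <- camera_model(1, 72, 1000, 750)
  expect_equal(ground_extent(cam72)[["diagonal"]], 2 * tan(36 * pi / 180))

  # extents shrink to zero with camera height
  tiny <- camera_model(1e-9, 72, 100, 100)
  expect_lt(max(ground_extent(tiny)), 1e-8)
})

test_that("extent identities hold over randomized cameras", {
  set.seed(11)
  for (i in 1:50) {
    cam <- camera_model(
      height_m = runif(1, 0.5, 120),
      aov_deg = runif(1, 10, 170),
      width_px = sample(100:6000, 1),
      height_px = sample(100:6000, 1)
    )
    ext <- ground_extent(cam)
    expect_equal(ext[["width"]]^2 + ext[["height"]]^2, ext[["diagonal"]]^2,
                 tolerance = 1e-9)
    expect_equal(ext[["width"]] / ext[["height"]],
                 cam$width_px / cam$height_px, tolerance = 1e-9)
    expect_gt(ext[["diagonal"]], 0)
  }
  # strictly increasing in H
  e1 <- ground_extent(camera_model(1, 72, 100, 100))
  e2 <- ground_extent(camera_model(2, 72, 100, 100))
  expect_gt(e2[["diagonal"]], e1[["diagonal"]])
})

test_that("invalid camera parameters are rejected", {
  expect_error(camera_model(0, 72, 100, 100), "height_m")
  expect_error(camera_model(-1, 72, 100, 100), "height_m")
  expect_error(camera_model(1, 0, 100, 100), "aov_deg")
  expect_error(camera_model(1, 180, 100, 100), "aov_deg")
  expect_error(camera_model(1, 72, 0, 100), "pixel")
  expect_error(camera_model(1, 72, 100.5, 100), "pixel")
})

test_that("pixel-to-metric maps corners, center and bounds correctly", {
  cam <- toy_cam()
  pts <- pixel_to_metric(
    data.frame(x = c(0, 1000, 500), y = c(0, 1000, 500)), cam
  )
  expect_equal(pts$x_m, c(0, cam$l_width_m, cam$l_width_m / 2))
  expect_equal(pts$y_m, c(0, cam$l_height_m, cam$l_height_m / 2))
  # image center is the nadir point
  expect_equal(unname(nadir_point(cam)),
               c(cam$l_width_m / 2, cam$l_height_m / 2))

  expect_error(pixel_to_metric(data.frame(x = -1, y = 0), cam), "outside")
  expect_warning(
    clamped <- pixel_to_metric(data.frame(x = 1200, y = 0), cam,
                               clamp = TRUE),
    "clamped"
  )
  expect_equal(clamped$x_m, cam$l_width_m)
})

test_that("metric distance obeys the classic identities", {
  expect_equal(metric_distance(0, 0, 3, 4), 5)
  expect_equal(metric_distance(1, 2, 1, 2), 0)
  # a 9 cm within-row interval measures 0.09 m
  expect_equal(metric_distance(0, 0, 0.09, 0), 0.09)

  set.seed(7)
  for (i in 1:100) {
    p <- matrix(runif(6, -10, 10), 3, 2)
    d12 <- metric_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d13 <- metric_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- metric_distance(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("pixel distances scale linearly with camera height", {
  px <- data.frame(x = c(100, 700), y = c(50, 600))
  d_at <- function(h) {
    m <- pixel_to_metric(px, camera_model(h, 72, 1000, 800))
    metric_distance(m$x_m[1], m$y_m[1], m$x_m[2], m$y_m[2])
  }
  expect_equal(d_at(4) / d_at(1), 4, tolerance = 1e-12)
  expect_equal(d_at(2.5) / d_at(0.5), 5, tolerance = 1e-12)
})

test_that("square-pixel sensors sample ground equally in x and y", {
  cam <- camera_model(3, 72, 640, 640)
  expect_equal(cam$l_width_m / cam$width_px, cam$l_height_m / cam$height_px)
  cam43 <- camera_model(3, 72, 960, 720)
  expect_equal(cam43$l_width_m / cam43$width_px,
               cam43$l_height_m / cam43$height_px)
})
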