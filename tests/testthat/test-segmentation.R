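test_that("EXG hits its extreme and neutral values", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(0, 1, 0)          # pure green
  img[1, 2, ] <- c(1, 0, 0)          # pure red
  img[2, 1, ] <- c(100, 100, 100) / 255 # gray (band maxima equal here)
  img[2, 2, ] <- c(1, 1, 1)          # white: forces equal band maxima
  exg <- compute_exg(img)
  expect_equal(exg[1, 1], 2)
  expect_equal(exg[1, 2], -1)
  expect_equal(exg[2, 1], 0)
  expect_equal(exg[2, 2], 0)
  expect_true(all(exg >= -1 & exg <= 2))
})

test_that("EXG is invariant to uniform brightness scaling", {
  set.seed(3)
  img <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  expect_equal(compute_exg(img * 0.37), compute_exg(img), tolerance = 1e-12)
})

test_that("EXG handles dropouts and rejects non-RGB input", {
  img <- array(0.5, dim = c(2, 2, 3))
  img[1, 1, ] <- 0 # dead pixel
  expect_equal(compute_exg(img)[1, 1], 0)
  expect_error(compute_exg(matrix(0.5, 3, 3)), "RGB")
  bad <- array(-0.1, dim = c(2, 2, 3))
  expect_error(compute_exg(bad), "negative")
})

test_that("thresholding separates two-level images and flags degenerates", {
  exg <- matrix(-0.5, 20, 20)
  exg[1:4, 1:20] <- 1.5 # 20% vegetation
  m <- threshold_vegetation(exg, "otsu")
  expect_equal(m, exg == 1.5, ignore_attr = TRUE)
  expect_true(attr(m, "threshold") > -0.5 && attr(m, "threshold") < 1.5)

  m0 <- threshold_vegetation(exg, "fixed", fixed_value = 0)
  expect_equal(m0, exg > 0, ignore_attr = TRUE)

  soil <- matrix(runif(100, -0.4, -0.1), 10, 10)
  expect_equal(sum(threshold_vegetation(soil, "fixed", fixed_value = 0)), 0)

  expect_error(threshold_vegetation(matrix(0.3, 5, 5), "otsu"), "degenerate")
  expect_error(threshold_vegetation(exg, "fixed"), "fixed_value")
})

test_that("object extraction uses 8-connectivity and half-pixel centroids", {
  # two disjoint 3x3 squares
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE
  m[10:12, 10:12] <- TRUE
  obj <- extract_objects(m)
  expect_equal(nrow(obj), 2)
  expect_equal(obj$area_px, c(9L, 9L))
  expect_equal(obj$object_id, 1:2) # raster order: top-left first

  # single pixel at 0-based (5, 5) -> centroid (5.5, 5.5)
  s <- matrix(FALSE, 20, 20)
  s[6, 6] <- TRUE
  one <- extract_objects(s)
  expect_equal(one$area_px, 1L)
  expect_equal(c(one$centroid_x_px, one$centroid_y_px), c(5.5, 5.5))
  expect_gt(one$perimeter_px, 0)

  # diagonal-touching pair is one component under 8-connectivity
  d <- mask_from_px(rbind(c(2, 2), c(3, 3)))
  expect_equal(nrow(extract_objects(d)), 1)

  expect_equal(nrow(extract_objects(matrix(FALSE, 5, 5))), 0)
})

test_that("centroids sit inside bounding boxes and masks are recoverable", {
  set.seed(21)
  m <- matrix(runif(40 * 40) < 0.2, 40, 40)
  obj <- extract_objects(m)
  labels <- attr(obj, "labels")
  expect_equal(sum(labels > 0), sum(m))
  for (i in seq_len(nrow(obj))) {
    px <- which(labels == obj$object_id[i], arr.ind = TRUE)
    expect_gte(obj$centroid_x_px[i], min(px[, 2]) - 1)
    expect_lte(obj$centroid_x_px[i], max(px[, 2]))
    expect_gte(obj$centroid_y_px[i], min(px[, 1]) - 1)
    expect_lte(obj$centroid_y_px[i], max(px[, 1]))
  }
})

test_that("area/shape filtering applies relative cutoffs", {
  # areas [100, 100, 100, 4], equal shapes: mean 76, cutoff 22.8 -> 3 survive
  obj <- fake_objects(c(100, 100, 100, 4))
  kept <- filter_objects(obj, t_area = 0.3, t_shape = 0.3)
  expect_equal(kept$object_id, 1:3)

  # a single object always survives its own mean
  expect_equal(nrow(filter_objects(fake_objects(50), 0.3, 0.3)), 1)

  # output is a subset of the input
  set.seed(5)
  obj2 <- fake_objects(sample(1:200, 30), shape = runif(30, 0.1, 2))
  kept2 <- filter_objects(obj2)
  expect_true(all(kept2$object_id %in% obj2$object_id))

  # empty in, empty out
  expect_equal(nrow(filter_objects(fake_objects(numeric(0)))), 0)

  # shape direction is configurable
  shp <- fake_objects(rep(100, 3), shape = c(0.1, 1, 5))
  expect_true(3 %in% filter_objects(shp, shape_keep = "above")$object_id)
  expect_true(1 %in% filter_objects(shp, shape_keep = "below")$object_id)
})

test_that("fragment merging joins near, keeps far, conserves pixels", {
  # two 3x3 fragments separated by a 2-pixel gap
  near <- matrix(FALSE, 20, 20)
  near[5:7, 3:5] <- TRUE
  near[5:7, 8:10] <- TRUE
  obj <- extract_objects(near)
  expect_equal(nrow(obj), 2)
  merged <- merge_fragments(obj, dilation_radius_px = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(sum(merged$area_px), sum(obj$area_px)) # pixel count conserved
  expect_gte(max(merged$area_px), max(obj$area_px))   # never shrinks

  # fragments 20 px apart stay separate
  far <- matrix(FALSE, 40, 40)
  far[5:7, 3:5] <- TRUE
  far[5:7, 25:27] <- TRUE
  objf <- extract_objects(far)
  expect_equal(nrow(merge_fragments(objf, dilation_radius_px = 2)), 2)

  # radius 0 is a no-op
  expect_identical(merge_fragments(objf, 0), objf)

  # merging is transitive along a chain of fragments
  chain <- matrix(FALSE, 20, 40)
  chain[9:11, c(3:5, 9:11, 15:17)] <- TRUE
  objc <- extract_objects(chain)
  expect_equal(nrow(objc), 3)
  expect_equal(nrow(merge_fragments(objc, 2)), 1)
})
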