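test_that("two exact parallel rows are recovered with full membership", {
  # 12 plants on 2 vertical lines 0.765 m apart
  x <- rep(c(1.0, 1.765), each = 6)
  y <- rep(seq(0.2, 1.2, length.out = 6), times = 2)
  plants <- plants_at(x, y)
  ridges <- detect_ridges(plants, angle_deg = 90, row_width_m = 0.765)
  expect_equal(nrow(ridges), 2)
  expect_equal(ridges$n_members, c(6L, 6L))
  # each ridge passes through its members' mean position
  expect_equal(ridges$anchor_x_m, c(1.0, 1.765), tolerance = 1e-12)
  # members are disjoint and cover all plants
  ids <- unlist(ridges$members)
  expect_setequal(ids, plants$object_id)
  expect_equal(anyDuplicated(ids), 0L)
  # vertical rows carry no slope/intercept form
  expect_true(all(is.na(ridges$k)))
})

test_that("a single plant seeds a single ridge through itself", {
  ridges <- detect_ridges(plants_at(0.5, 0.7), 45, row_width_m = 0.5)
  expect_equal(nrow(ridges), 1)
  expect_equal(c(ridges$anchor_x_m, ridges$anchor_y_m), c(0.5, 0.7))
  expect_equal(ridges$angle_rad, pi / 4)
  expect_false(is.na(ridges$k))
  expect_equal(nrow(detect_ridges(plants_at(numeric(0), numeric(0)),
                                  90, 0.5)), 0)
})

test_that("jittered rows are recovered near the least-squares oracle", {
  w <- 0.765
  set.seed(17)
  true_off <- c(0.8, 0.8 + w, 0.8 + 2 * w)
  pts <- do.call(rbind, lapply(seq_along(true_off), function(k) {
    n <- 8
    cbind(x = true_off[k] + runif(n, -w / 10, w / 10),
          y = seq(0.1, 2.0, length.out = n), g = k)
  }))
  plants <- plants_at(pts[, "x"], pts[, "y"])
  ridges <- detect_ridges(plants, 90, w)
  expect_equal(nrow(ridges), 3)
  # oracle: with a fixed vertical direction, the least-squares line through a
  # group is x = mean(x); ridge offsets must sit within the jitter amplitude
  for (k in seq_along(true_off)) {
    oracle <- mean(pts[pts[, "g"] == k, "x"])
    # ridges sort by signed offset, which equals x for vertical rows
    expect_lt(abs(ridges$offset_m[k] - oracle), w / 10)
  }
})

test_that("ridge offsets are stable across random seed orders", {
  w <- 0.5
  set.seed(23)
  x <- rep(c(0.5, 1.0, 1.5), each = 7) + rnorm(21, 0, 0.01)
  y <- rep(seq(0.1, 1.3, length.out = 7), 3)
  plants <- plants_at(x, y)
  ref <- sort(detect_ridges(plants, 90, w)$offset_m)
  for (i in 1:20) {
    set.seed(100 + i)
    got <- sort(detect_ridges(plants, 90, w, seed_method = "random")$offset_m)
    expect_equal(length(got), 3)
    expect_true(all(abs(got - ref) < w / 3))
  }
})

test_that("ridge count matches truth when rows are well separated", {
  for (seed in 1:5) {
    sc <- small_indoor_scene(seed = seed)
    plants <- plants_at(sc$truth$stems$x_m, sc$truth$stems$y_m)
    ridges <- detect_ridges(plants, 90, sc$spec$row_width_m)
    expect_equal(nrow(ridges), nrow(sc$truth$rows))
  }
})

test_that("weed filtering partitions plants by ridge distance", {
  plants <- plants_at(c(1.0, 1.02, 1.0, 1.6), c(0.2, 0.6, 1.0, 0.6))
  ridges <- detect_ridges(plants[1:3, ], 90, 0.76)
  out <- filter_weeds(plants, ridges, tolerance_m = 0.2)
  expect_equal(out$weed, c(FALSE, FALSE, FALSE, TRUE))
  # partition: kept + removed = input, disjoint by construction of a flag
  expect_equal(sum(out$weed) + sum(!out$weed), nrow(plants))
  # plant exactly on a ridge is kept; 3x tolerance away is removed
  expect_equal(out$dist_to_ridge_m[1], abs(1.0 - mean(c(1.0, 1.02, 1.0))),
               tolerance = 1e-12)
  expect_gt(out$dist_to_ridge_m[4], 3 * 0.19)

  expect_warning(all_weeds <- filter_weeds(plants, ridges[0, ], 0.2),
                 "no ridges")
  expect_true(all(all_weeds$weed))
})

test_that("sparse weed ridges are pruned, populated crop rows kept", {
  x <- c(rep(1.0, 8), rep(1.53, 8), 1.25, 1.27)
  y <- c(seq(0.1, 1.5, length.out = 8), seq(0.1, 1.5, length.out = 8),
         0.4, 1.1)
  ridges <- detect_ridges(plants_at(x, y), 90, 0.53)
  expect_equal(nrow(ridges), 3)
  pruned <- prune_ridges(ridges, min_members = 2, member_frac = 0.3)
  expect_equal(nrow(pruned), 2)
  expect_equal(pruned$n_members, c(8L, 8L))
  expect_equal(pruned$ridge_id, 1:2)
})

test_that("extra refinement passes can collect stragglers", {
  # seed sits off-line at 1.06; one pass reaches the plants at 0.95 but not
  # the straggler at 0.90; after recentring, a second pass collects it too
  x <- c(rep(0.95, 4), 0.90, 1.06)
  y <- c(0.2, 0.5, 0.8, 1.1, 0.35, 0.65)
  plants <- plants_at(x, y)
  r1 <- detect_ridges(plants, 90, 0.36, center = c(1.06, 0.65))
  r5 <- detect_ridges(plants, 90, 0.36, center = c(1.06, 0.65),
                      refine_iters = 5)
  expect_equal(max(r1$n_members), 5L)
  expect_equal(max(r5$n_members), 6L)
  expect_lt(nrow(r5), nrow(r1))
})
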