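# Phosphene map construction, activation pooling, and blob rendering.

test_that("map geometry: counts, pitch, and degenerate noise", {
  spec <- phosphene_grid_spec(26)
  map <- build_phosphene_map(spec)
  expect_equal(nrow(map$locations), 676L)
  expect_equal(map$pitch, 480 / 26)
  spec0 <- phosphene_grid_spec(10, jitter_frac = 0, gain_sd = 0)
  map0 <- build_phosphene_map(spec0)
  expect_equal(map0$locations, map0$base_locations)
  expect_true(all(map0$gains == 1))
})

test_that("jitter never exceeds its bound (exhaustive over phosphenes)", {
  for (seed in c(1, 99, 2024)) {
    spec <- phosphene_grid_spec(18, jitter_frac = 0.15, seed = seed)
    map <- build_phosphene_map(spec)
    disp <- abs(map$locations - map$base_locations)
    expect_lte(max(disp), 0.15 * map$pitch + 1e-12)
    expect_true(all(map$gains > 0))
  }
})

test_that("maps are reproducible under seed and differ across seeds", {
  s <- phosphene_grid_spec(26, seed = 5)
  expect_identical(build_phosphene_map(s), build_phosphene_map(s))
  s2 <- phosphene_grid_spec(26, seed = 6)
  expect_false(identical(build_phosphene_map(s)$locations,
                         build_phosphene_map(s2)$locations))
})

test_that("activation matches brute-force window membership", {
  set.seed(21)
  for (rep in 1:6) {
    spec <- phosphene_grid_spec(sample(c(10, 18, 26), 1),
                                jitter_frac = runif(1, 0, 0.3), seed = rep)
    map <- build_phosphene_map(spec)
    mask <- matrix(0L, 480, 480)
    mask[sample(480 * 480, 800)] <- 1L
    for (policy in c("max_pool", "mean_pool")) {
      got <- activate_phosphenes(map, mask, policy, mean_threshold = 0.002)
      want <- bf_activation(map, mask, policy, mean_threshold = 0.002)
      expect_identical(got, want)
    }
  }
})

test_that("activation edge cases: empty, full, single pixel", {
  spec <- phosphene_grid_spec(10, jitter_frac = 0)
  map <- build_phosphene_map(spec)
  expect_false(any(activate_phosphenes(map, matrix(0L, 480, 480))))
  expect_true(all(activate_phosphenes(map, matrix(1L, 480, 480))))
  expect_true(all(activate_phosphenes(map, matrix(1L, 480, 480), "mean_pool",
                                      mean_threshold = 1)))
  mask <- matrix(0L, 480, 480); mask[100, 200] <- 1L
  a <- activate_phosphenes(map, mask)
  expect_identical(which(a), which(bf_activation(map, mask)))
  expect_equal(sum(a), 1L)
  expect_error(activate_phosphenes(map, matrix(0L, 100, 100)), "mask must be")
})

test_that("adding mask pixels never turns a max-pool phosphene off", {
  set.seed(4)
  spec <- phosphene_grid_spec(18, seed = 2)
  map <- build_phosphene_map(spec)
  m1 <- matrix(0L, 480, 480); m1[sample(480 * 480, 500)] <- 1L
  m2 <- m1; m2[sample(480 * 480, 500)] <- 1L
  a1 <- activate_phosphenes(map, m1)
  a2 <- activate_phosphenes(map, m2)
  expect_true(all(a2[a1]))
})

test_that("rendered blobs follow the closed-form Gaussian and superpose", {
  spec <- phosphene_grid_spec(10, jitter_frac = 0, gain_sd = 0)
  map <- build_phosphene_map(spec)
  act <- rep(FALSE, 100); act[45] <- TRUE
  fr <- render_phosphenes(map, act)
  loc <- map$locations[45, ]
  # closed-form blob: gain * exp(-d^2 / (2 sigma^2)), sigma = 2
  for (px in list(c(0, 0), c(0, 2), c(1, 1), c(2, 0))) {
    row <- round(loc[["y"]] + 0.5) + px[1]
    col <- round(loc[["x"]] + 0.5) + px[2]
    d2 <- ((col - 0.5) - loc[["x"]])^2 + ((row - 0.5) - loc[["y"]])^2
    expect_equal(fr$image[row, col], exp(-d2 / 8), tolerance = 1e-9)
  }
  expect_gt(fr$image[round(loc[["y"]] + 0.5), round(loc[["x"]] + 0.5)], 0.9)
  # no active phosphenes -> zero image
  expect_equal(sum(render_phosphenes(map, rep(FALSE, 100))$image), 0)
  # superposition for distant phosphenes
  act2 <- rep(FALSE, 100); act2[10] <- TRUE
  both <- rep(FALSE, 100); both[c(45, 10)] <- TRUE
  expect_equal(render_phosphenes(map, both)$image,
               render_phosphenes(map, act)$image +
                 render_phosphenes(map, act2)$image, tolerance = 1e-12)
  expect_error(render_phosphenes(map, rep(TRUE, 99)), "length")
})

test_that("blob angular size at defaults is about 0.3 degrees", {
  expect_equal(blob_angular_size_deg(phosphene_grid_spec(26)),
               2 * 2.0 * 35 / 480)
  expect_equal(blob_angular_size_deg(phosphene_grid_spec(26)), 0.29,
               tolerance = 0.01)
})

test_that("simulation is deterministic and temporally constant", {
  lay <- single_box_layout("large", 1.2, 6)
  v <- render_view(corridor_spec(), lay, camera_pose(c(1.5, 1, 1.6)))
  spec <- phosphene_grid_spec(26, seed = 9)
  f1 <- simulate_view(v, spec)
  f2 <- simulate_view(v, spec)
  expect_identical(f1, f2)
  expect_equal(sum(simulate_view(matrix(0.5, 480, 480), spec)$activations), 0)
})

test_that("higher resolution covers the contour more densely", {
  lay <- single_box_layout("large", 1.2, 6)
  v <- render_view(corridor_spec(), lay, camera_pose(c(1.5, 1, 1.6)))
  mask <- extract_contours(v, "boundary_oracle")
  mean_dist <- function(n) {
    spec <- phosphene_grid_spec(n, seed = 1)
    map <- build_phosphene_map(spec)
    act <- activate_phosphenes(map, mask)
    pts <- map$locations[act, , drop = FALSE]
    cont <- which(mask > 0, arr.ind = TRUE)
    cont <- cont[seq(1, nrow(cont), by = 4), , drop = FALSE]
    d2 <- outer(cont[, 2], pts[, "x"], `-`)^2 +
      outer(cont[, 1], pts[, "y"], `-`)^2
    mean(sqrt(apply(d2, 1, min)))
  }
  expect_lt(mean_dist(50), mean_dist(10))
})

test_that("a symmetric mask renders a symmetric percept at zero jitter", {
  spec <- phosphene_grid_spec(9, jitter_frac = 0, gain_sd = 0,
                              display_px = 90)
  map <- build_phosphene_map(spec)
  mask <- matrix(0L, 90, 90)
  mask[20:71, 45:46] <- 1L; mask[45:46, 20:71] <- 1L  # symmetric cross
  act <- activate_phosphenes(map, mask)
  img <- render_phosphenes(map, act)$image
  expect_equal(img, img[, ncol(img):1], tolerance = 1e-12)
  expect_equal(img, t(img), tolerance = 1e-12)
})
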