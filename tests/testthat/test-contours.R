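# Preprocessing, Gaussian smoothing, Canny edge detection, boundary
# combination and the extraction dispatcher.

test_that("preprocess is the identity on 480x480 input and preserves constants", {
  m <- matrix(runif(480 * 480), 480, 480)
  expect_equal(preprocess(m), m)
  cm <- matrix(0.4, 300, 520)
  out <- preprocess(cm)
  expect_equal(dim(out), c(480L, 480L))
  expect_equal(range(out), c(0.4, 0.4))
  expect_error(preprocess(numeric(0)), "empty")
})

test_that("preprocess center-crops then resamples (960x720 case)", {
  # 720 rows x 960 cols linear column ramp: crop keeps cols 121..840, and
  # bilinear resampling of a linear ramp reproduces the ramp exactly.
  frame <- matrix(rep(seq_len(960), each = 720) / 960, 720, 960)
  out <- preprocess(frame)
  expect_equal(dim(out), c(480L, 480L))
  # output column j center maps to input column position 120 + (j-0.5)*1.5
  j <- c(1, 120, 240, 480)
  expected <- (120 + (j - 0.5) * 1.5 + 0.5) / 960
  expect_equal(out[240, j], expected, tolerance = 1e-9)
})

test_that("grayscale conversion uses 601 luma weights", {
  arr <- array(0, c(2, 2, 3))
  arr[, , 1] <- 1
  expect_equal(to_gray(arr)[1, 1], 0.299)
  arr2 <- array(1, c(2, 2, 3))
  expect_equal(to_gray(arr2)[1, 1], 1)
})

test_that("gaussian smoothing reproduces the closed-form kernel and preserves DC", {
  # impulse response
  n <- 41L
  img <- matrix(0, n, n); img[21, 21] <- 1
  sm <- gaussian_smooth(img, 3.0)
  rad <- ceiling(4 * 3.0)
  k <- exp(-(seq(-rad, rad))^2 / 18); k <- k / sum(k)
  expected <- outer(k, k)
  got <- sm[(21 - rad):(21 + rad), (21 - rad):(21 + rad)]
  expect_lt(max(abs(got - expected)) / max(expected), 1e-6)
  # total intensity conserved for interior-supported content
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  # constant frame unchanged
  cst <- matrix(0.7, 20, 20)
  expect_equal(gaussian_smooth(cst, 2.5), cst, tolerance = 1e-12)
  expect_error(gaussian_smooth(cst, 0), "sigma")
})

test_that("canny on a uniform frame is empty", {
  expect_equal(sum(canny_edges(matrix(0.5, 100, 100))), 0)
})

test_that("canny traces a centered square as a thin closed contour", {
  img <- matrix(0, 100, 100)
  img[31:70, 31:70] <- 1
  mask <- canny_edges(img)
  expect_gt(sum(mask), 100)
  # every mask pixel within 2 px (Chebyshev) of the true perimeter
  idx <- which(mask > 0, arr.ind = TRUE)
  on_perim <- function(i, j) {
    near <- function(a, lo, hi) a >= lo - 2 & a <= hi + 2
    inside <- near(i, 31, 70) & near(j, 31, 70)
    at_edge <- abs(i - 30.5) <= 2.5 | abs(i - 70.5) <= 2.5 |
      abs(j - 30.5) <= 2.5 | abs(j - 70.5) <= 2.5
    inside & at_edge
  }
  expect_true(all(on_perim(idx[, 1], idx[, 2])))
  # single 8-connected component: flood fill from one edge pixel reaches all
  seed_mag <- mask * 30
  seed_mag[idx[1, 1], idx[1, 2]] <- 60
  comp <- bf_hysteresis(seed_mag, 25, 50)
  expect_equal(sum(comp), sum(mask))
  rows_mid <- 40:60
  expect_true(all(vapply(rows_mid, function(i)
    any(idx[, 1] == i & idx[, 2] < 50) && any(idx[, 1] == i & idx[, 2] > 50),
    logical(1))))
})

test_that("canny masks are monotone in the hysteresis thresholds", {
  set.seed(42)
  img <- gaussian_smooth(matrix(runif(80 * 80), 80, 80), 2)
  lo <- canny_edges(img, canny_params(sigma = 2, low = 10, high = 25))
  hi <- canny_edges(img, canny_params(sigma = 2, low = 25, high = 50))
  expect_true(all(lo[hi > 0] == 1))
  expect_gt(sum(lo), sum(hi))
})

test_that("hysteresis equals the flood-fill oracle on random gradient fields", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(8:32, 1)
    mag <- matrix(0, n, n)
    k <- sample(3:12, 1)
    mag[sample(n * n, k)] <- runif(k, 0, 255)
    # sprinkle connected weak structure
    mag <- pmax(mag, gaussian_smooth(mag, 1) * 3)
    got <- spvsim:::hysteresis(mag, 25, 50)
    want <- bf_hysteresis(mag, 25, 50)
    expect_identical(unclass(got), want)
  }
})

test_that("rotating the frame by 90 degrees rotates the edge mask", {
  set.seed(3)
  img <- gaussian_smooth(matrix(runif(120 * 120), 120, 120), 3)
  rot90 <- function(m) t(m)[, nrow(m):1]  # counter-clockwise? fixed mapping
  m1 <- canny_edges(img)
  m2 <- canny_edges(rot90(img))
  expect_identical(unclass(rot90(m1)), unclass(m2))
})

test_that("boundary combination matches the per-pixel threshold rule", {
  set.seed(11)
  prob <- matrix(0, 64, 64)
  prob[sample(64 * 64, 200)] <- runif(200, 0, 255)
  flat <- array(0, c(64, 64, 3)); flat[, , 3] <- 1
  pred <- boundary_prediction(prob, flat)
  mask <- combine_boundary_predictions(pred, boundary_params())
  expect_identical(unclass(mask), unclass((prob > 94) + 0L))
  # zero probability + constant normals -> empty
  pred0 <- boundary_prediction(matrix(0, 64, 64), flat)
  expect_equal(sum(combine_boundary_predictions(pred0)), 0)
  # monotone in the threshold
  m_lo <- combine_boundary_predictions(pred, boundary_params(50))
  m_hi <- combine_boundary_predictions(pred, boundary_params(150))
  expect_true(all(m_lo[m_hi > 0] == 1))
  # misalignment is a contract error
  expect_error(boundary_prediction(matrix(0, 10, 12), array(0, c(10, 10, 3))),
               "misaligned")
})

test_that("normal-map contours contribute to the combined mask", {
  normals <- array(0, c(64, 64, 3))
  normals[, 1:32, 1] <- 1          # left half faces +x
  normals[, 33:64, 3] <- 1         # right half faces +z
  pred <- boundary_prediction(matrix(0, 64, 64), normals)
  mask <- combine_boundary_predictions(pred)
  idx <- which(mask > 0, arr.ind = TRUE)
  expect_gt(nrow(idx), 30)
  expect_true(all(abs(idx[, 2] - 32.5) <= 4))
})

test_that("extraction dispatches and validates methods", {
  expect_error(extract_contours(matrix(0, 10, 10), "nonsense"),
               "unknown contour method")
  expect_error(extract_contours(matrix(0, 480, 480), "boundary_oracle"),
               "rendered_view")
  expect_error(extract_contours(matrix(0, 480, 480), "boundary_external"),
               "boundary_prediction")
})

test_that("complex scenes yield strictly more CED pixels than plain scenes", {
  lay <- single_box_layout("large", 1.0, 6)
  pose <- camera_pose(c(1.5, 1, 1.6))
  vp <- render_view(corridor_spec(complexity = "plain"), lay, pose)
  vc <- render_view(corridor_spec(complexity = "complex"), lay, pose)
  mp <- extract_contours(vp, "ced")
  mc <- extract_contours(vc, "ced")
  expect_gt(sum(mc), sum(mp))
})

test_that("masks round-trip through PNG", {
  m <- matrix(0L, 32, 32); m[5:10, 5:10] <- 1L
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  back <- read_mask_png(path)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
})
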