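# Contour extraction: the scene-simplification front end. An input frame is
# reduced to a binary 480x480 contour mask either by Canny edge detection
# (gradients from all of the scene, textures included) or by surface-boundary
# detection (depth/normal discontinuities only).

#' Canny parameters
#'
#' @param sigma Gaussian smoothing scale in pixels (default 3.0).
#' @param low,high Hysteresis thresholds on the 8-bit gradient-magnitude
#'   scale (defaults 25 and 50 out of 255).
#' @return A `canny_params` list.
#' @export
canny_params <- function(sigma = 3.0, low = 25, high = 50) {
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  check_number(low, "low", 0, 255)
  check_number(high, "high", 0, 255)
  if (low > high) stop_contract("`low` must be <= `high`")
  structure(list(sigma = sigma, low = low, high = high),
            class = "canny_params")
}

#' Boundary-combination parameters
#'
#' @param boundary_threshold 8-bit threshold on the boundary-probability map
#'   (default 94 out of 255).
#' @param normal_contour_params [canny_params()] applied to the surface
#'   normal map (default sigma 1.0, thresholds 25/50).
#' @return A `boundary_params` list.
#' @export
boundary_params <- function(boundary_threshold = 94,
                            normal_contour_params = canny_params(sigma = 1.0)) {
  check_number(boundary_threshold, "boundary_threshold", 0, 255)
  structure(list(boundary_threshold = boundary_threshold,
                 normal_contour_params = normal_contour_params),
            class = "boundary_params")
}

# Normalize any frame (matrix or HxWx3 array, [0,1] doubles or 0-255) to
# [0,1] doubles.
as_unit_frame <- function(frame) {
  if (is.null(dim(frame)) || length(frame) == 0L)
    stop_contract("empty frame")
  frame <- frame * 1.0
  if (max(frame, na.rm = TRUE) > 1.5) frame <- frame / 255
  frame
}

#' Grayscale conversion (ITU-R 601 luma)
#'
#' @param frame `H x W x 3` array in `[0, 1]` (a grayscale matrix passes
#'   through unchanged).
#' @return `H x W` matrix.
#' @export
to_gray <- function(frame) {
  frame <- as_unit_frame(frame)
  if (length(dim(frame)) == 2L) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

bilinear_resize <- function(m, out) {
  nr <- nrow(m); nc <- ncol(m)
  map <- function(i, n_in, n_out) {
    pos <- (i - 0.5) * n_in / n_out + 0.5
    lo <- clamp(floor(pos), 1, n_in); hi <- clamp(lo + 1, 1, n_in)
    list(lo = lo, hi = hi, w = pos - lo)
  }
  r <- map(seq_len(out), nr, out); c <- map(seq_len(out), nc, out)
  top <- m[r$lo, c$lo, drop = FALSE] * (1 - c$w[col(matrix(0, out, out))]) +
    m[r$lo, c$hi, drop = FALSE] * c$w[col(matrix(0, out, out))]
  bot <- m[r$hi, c$lo, drop = FALSE] * (1 - c$w[col(matrix(0, out, out))]) +
    m[r$hi, c$hi, drop = FALSE] * c$w[col(matrix(0, out, out))]
  wr <- r$w[row(matrix(0, out, out))]
  top * (1 - wr) + bot * wr
}

#' Preprocess a camera frame
#'
#' Center-crops the frame to a square and bilinearly resamples it to
#' `size x size` pixels (default 480); optionally converts to grayscale
#' luminance for the edge-detection path.
#'
#' @param frame Matrix or `H x W x 3` array.
#' @param size Output side in pixels (default 480).
#' @param gray Convert to grayscale (default FALSE).
#' @return `size x size` matrix or `size x size x 3` array in `[0, 1]`.
#' @export
preprocess <- function(frame, size = 480L, gray = FALSE) {
  frame <- as_unit_frame(frame)
  if (gray) frame <- to_gray(frame)
  crop1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m); side <- min(nr, nc)
    r0 <- floor((nr - side) / 2); c0 <- floor((nc - side) / 2)
    m[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
  }
  if (length(dim(frame)) == 2L) {
    m <- crop1(frame)
    if (nrow(m) == size) return(m)
    return(bilinear_resize(m, size))
  }
  out <- array(0, c(size, size, dim(frame)[3]))
  for (ch in seq_len(dim(frame)[3])) {
    m <- crop1(frame[, , ch])
    out[, , ch] <- if (nrow(m) == size) m else bilinear_resize(m, size)
  }
  out
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized sampled Gaussian kernel truncated
#' at four standard deviations, with reflective border handling.
#'
#' @param img Matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(img, sigma) {
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  acc <- 0
  for (o in seq(-rad, rad))
    acc <- acc + k[o + rad + 1L] * shift_reflect(img, 0L, o)
  out <- 0
  for (o in seq(-rad, rad))
    out <- out + k[o + rad + 1L] * shift_reflect(acc, o, 0L)
  out
}

# Sobel gradients (3x3, L2 magnitude). gx increases with column index, gy
# with row index.
sobel_gradients <- function(m) {
  sx <- function(mm)
    (shift_reflect(mm, -1L, 1L) + 2 * shift_reflect(mm, 0L, 1L) +
       shift_reflect(mm, 1L, 1L)) -
    (shift_reflect(mm, -1L, -1L) + 2 * shift_reflect(mm, 0L, -1L) +
       shift_reflect(mm, 1L, -1L))
  gx <- sx(m)
  gy <- t(sx(t(m)))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Non-maximum suppression along the quantized gradient direction.
nms <- function(mag, gx, gy) {
  theta <- atan2(gy, gx) * 180 / pi
  theta <- theta %% 180
  sector <- as.integer(floor((theta + 22.5) / 45)) %% 4L
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    sel <- sector == s
    if (!any(sel)) next
    a <- shift_reflect(mag, o[1], o[2])
    b <- shift_reflect(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  out <- mag
  out[!keep] <- 0
  out
}

# Hysteresis linking: candidate pixels (> low) survive iff their 8-connected
# candidate component contains a strong pixel (> high).
hysteresis <- function(mag, low, high) {
  strong <- mag > high
  cand <- mag > low
  res_r <- nrow(mag); res_c <- ncol(mag)
  if (!any(strong)) return(matrix(0L, res_r, res_c))
  id <- matrix(seq_len(res_r * res_c), res_r, res_c)
  from <- integer(0); to <- integer(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    di <- o[1]; dj <- o[2]
    ra <- seq_len(res_r - di)
    ca <- if (dj >= 0) seq_len(res_c - dj) else seq(1 - dj, res_c)
    a <- cand[ra, ca, drop = FALSE] & cand[ra + di, ca + dj, drop = FALSE]
    from <- c(from, id[ra, ca, drop = FALSE][a])
    to <- c(to, id[ra + di, ca + dj, drop = FALSE][a])
  }
  g <- igraph::make_empty_graph(n = res_r * res_c, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  keep_comp <- unique(memb[which(strong)])
  out <- matrix(0L, res_r, res_c)
  out[cand & matrix(memb %in% keep_comp, res_r, res_c)] <- 1L
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, 3x3 Sobel gradients with L2 magnitude, non-maximum
#' suppression along the quantized gradient direction, and dual-threshold
#' hysteresis: a pixel is an edge when its gradient exceeds the upper
#' threshold, or exceeds the lower threshold and is 8-connected (through
#' other above-lower pixels) to one that exceeds the upper threshold.
#' Thresholds are on the 8-bit scale: the image is mapped to 0-255 before
#' gradient computation.
#'
#' @param img Grayscale matrix (values in `[0, 1]` or 0-255).
#' @param params A [canny_params()].
#' @return Binary matrix of class `contour_mask`.
#' @export
canny_edges <- function(img, params = canny_params()) {
  if (length(dim(img)) != 2L) stop_contract("`img` must be a grayscale matrix")
  m <- as_unit_frame(img) * 255
  sm <- gaussian_smooth(m, params$sigma)
  g <- sobel_gradients(sm)
  supp <- nms(g$mag, g$gx, g$gy)
  structure(hysteresis(supp, params$low, params$high),
            class = c("contour_mask", "matrix"))
}

#' Boundary prediction container
#'
#' The contract for plugging any external surface-boundary / normal
#' predictor into the pipeline: an 8-bit boundary-probability map plus a
#' surface-normal map over the same raster.
#'
#' @param boundary_prob Matrix with values in `[0, 255]`.
#' @param normals `H x W x 3` array of (approximately unit) normals.
#' @return A `boundary_prediction` list.
#' @export
boundary_prediction <- function(boundary_prob, normals) {
  if (!all(dim(boundary_prob) == dim(normals)[1:2]))
    stop_contract("boundary_prob and normals are misaligned")
  if (min(boundary_prob) < 0 || max(boundary_prob) > 255)
    stop_contract("boundary_prob must lie in [0, 255]")
  structure(list(boundary_prob = boundary_prob, normals = normals),
            class = "boundary_prediction")
}

#' Combine boundary and normal-map predictions into a contour mask
#'
#' Reproduces the surface-boundary pipeline: the thresholded boundary
#' probability map is OR-combined with Canny-style contours of the surface
#' normal map (Canny applied to each normal component, union of the
#' per-component masks).
#'
#' @param pred A [boundary_prediction()].
#' @param params A [boundary_params()].
#' @return Binary matrix of class `contour_mask`.
#' @export
combine_boundary_predictions <- function(pred, params = boundary_params()) {
  stopifnot(inherits(pred, "boundary_prediction"))
  mask <- pred$boundary_prob > params$boundary_threshold
  for (ch in seq_len(dim(pred$normals)[3])) {
    comp <- (pred$normals[, , ch] + 1) / 2  # [-1, 1] -> [0, 1]
    if (max(comp) - min(comp) < 1e-12) next  # constant channel: no contours
    mask <- mask | (canny_edges(comp, params$normal_contour_params) > 0)
  }
  structure(mask + 0L, class = c("contour_mask", "matrix"))
}

#' Extract a contour mask from a frame or rendered view
#'
#' Dispatch over the two scene-simplification strategies plus the adapter
#' for external predictors:
#' \describe{
#'   \item{`ced`}{Canny edge detection on the (grayscale) frame.}
#'   \item{`boundary_oracle`}{Geometry-derived surface boundaries of a
#'     [render_view()] result (requires depth/normal channels).}
#'   \item{`boundary_external`}{[combine_boundary_predictions()] on a
#'     caller-supplied [boundary_prediction()].}
#' }
#'
#' @param x An image frame, `rendered_view`, or `boundary_prediction`.
#' @param method One of `"ced"`, `"boundary_oracle"`, `"boundary_external"`.
#' @param params [canny_params()] or [boundary_params()] as appropriate
#'   (`NULL` for defaults); for `boundary_oracle`, a list with elements
#'   `depth_jump_frac` and `normal_angle_deg`.
#' @return Binary matrix of class `contour_mask`.
#' @export
extract_contours <- function(x, method = c("ced", "boundary_oracle",
                                           "boundary_external"),
                             params = NULL) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_contract(
                       "unknown contour method '%s'", paste(method[1])))
  switch(method,
    ced = {
      img <- if (inherits(x, "rendered_view")) to_gray(x$rgb) else
        preprocess(x, gray = TRUE)
      canny_edges(img, params %||% canny_params())
    },
    boundary_oracle = {
      if (!inherits(x, "rendered_view") || is.null(x$depth) ||
          is.null(x$normals))
        stop_contract("boundary_oracle requires a rendered_view with depth and normals")
      p <- params %||% list()
      ground_truth_boundaries(x,
        depth_jump_frac = p$depth_jump_frac %||% 0.05,
        normal_angle_deg = p$normal_angle_deg %||% 20)
    },
    boundary_external = {
      if (!inherits(x, "boundary_prediction"))
        stop_contract("boundary_external requires a boundary_prediction object")
      combine_boundary_predictions(x, params %||% boundary_params())
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tolerant contour-mask agreement (precision, recall, F1)
#'
#' Matches mask pixels to reference pixels within a Chebyshev pixel
#' tolerance: precision is the fraction of mask pixels within `tol_px` of a
#' reference pixel, recall the fraction of reference pixels within `tol_px`
#' of a mask pixel.
#'
#' @param mask,reference Binary matrices of equal size.
#' @param tol_px Matching tolerance in pixels (default 2).
#' @return List with `precision`, `recall`, `f1`.
#' @export
mask_f1 <- function(mask, reference, tol_px = 2L) {
  stopifnot(all(dim(mask) == dim(reference)))
  dil <- function(m, r) {
    out <- m > 0
    acc <- out
    for (di in -r:r) for (dj in -r:r)
      if (di || dj) acc <- acc | shift_reflect(out, di, dj)
    acc
  }
  ref_d <- dil(reference, tol_px)
  mask_d <- dil(mask, tol_px)
  np <- sum(mask > 0); nr <- sum(reference > 0)
  precision <- if (np == 0) NA_real_ else sum(mask > 0 & ref_d) / np
  recall <- if (nr == 0) NA_real_ else sum(reference > 0 & mask_d) / nr
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Read / write contour masks as PNG
#'
#' Masks are stored as 8-bit PNG with values 0/255.
#'
#' @param mask Binary matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a binary `contour_mask` matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure((m > 0.5) + 0L, class = c("contour_mask", "matrix"))
}
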