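# Binary phosphene simulation: a contour mask drives an n x n grid of
# simulated cortical phosphenes, rendered as white Gaussian blobs with
# jittered locations and temporally constant per-phosphene brightness gains.

#' Phosphene grid specification
#'
#' The study resolutions are 10, 18, 26, 34, 42 and 50 phosphenes per side on
#' a 480 x 480 display spanning roughly 35 degrees of visual angle; blobs
#' have a Gaussian sigma of 2 pixels, i.e. an angular size of about 0.3
#' degrees (see [blob_angular_size_deg()]). Grid-location jitter and the
#' brightness-gain spread emulate biological irregularities in phosphene
#' mapping; both are frozen per seed and constant over time.
#'
#' @param n Phosphenes per row/column (>= 1).
#' @param display_px Display raster side in pixels (default 480).
#' @param fov_deg Display visual angle in degrees (default 35).
#' @param blob_sigma_px Gaussian blob sigma in pixels (default 2.0).
#' @param jitter_frac Maximum per-axis location jitter as a fraction of the
#'   grid pitch, in `[0, 0.5)` (default 0.15).
#' @param gain_sd Spread of the per-phosphene brightness gain (normal around
#'   1, clipped to `[0.5, 1.5]`; default 0.1).
#' @param seed Integer seed freezing jitter and gains.
#' @return A `phosphene_grid_spec` list.
#' @export
phosphene_grid_spec <- function(n, display_px = 480L, fov_deg = 35,
                                blob_sigma_px = 2.0, jitter_frac = 0.15,
                                gain_sd = 0.1, seed = 1L) {
  check_number(n, "n", 1)
  check_number(blob_sigma_px, "blob_sigma_px", 0, strict_lower = TRUE)
  check_number(jitter_frac, "jitter_frac", 0, 0.5)
  if (jitter_frac >= 0.5) stop_contract("`jitter_frac` must be < 0.5")
  check_number(gain_sd, "gain_sd", 0)
  structure(list(n = as.integer(n), display_px = as.integer(display_px),
                 fov_deg = fov_deg, blob_sigma_px = blob_sigma_px,
                 jitter_frac = jitter_frac, gain_sd = gain_sd,
                 seed = as.integer(seed)),
            class = "phosphene_grid_spec")
}

#' Angular blob size at a grid specification
#'
#' Full width (2 sigma) of a phosphene blob expressed in degrees of visual
#' angle: `2 * blob_sigma_px * fov_deg / display_px`. About 0.29 degrees at
#' the defaults.
#'
#' @param spec A [phosphene_grid_spec()].
#' @return Angular size in degrees.
#' @export
blob_angular_size_deg <- function(spec) {
  2 * spec$blob_sigma_px * spec$fov_deg / spec$display_px
}

#' Build a phosphene map
#'
#' Places `n^2` phosphenes at the cell centers of a uniform `n x n` partition
#' of the display, applies uniform location jitter within
#' `jitter_frac * pitch` per axis, and draws per-phosphene brightness gains
#' from a normal distribution with mean 1 and SD `gain_sd`, clipped to
#' `[0.5, 1.5]`. All draws come from a generator seeded by `spec$seed`, so
#' the map is reproducible and temporally constant across a frame stream.
#'
#' @param spec A [phosphene_grid_spec()].
#' @return A `phosphene_map`: list with `base_locations` and `locations`
#'   (`n^2 x 2` matrices of pixel coordinates, columns `x` = column
#'   coordinate and `y` = row coordinate, half-integer pixel centers),
#'   `gains`, `pitch` and `spec`.
#' @export
build_phosphene_map <- function(spec) {
  stopifnot(inherits(spec, "phosphene_grid_spec"))
  n <- spec$n
  pitch <- spec$display_px / n
  centers <- (seq_len(n) - 0.5) * pitch
  base <- cbind(x = rep(centers, times = n), y = rep(centers, each = n))
  run_seeded(spec$seed, {
    jit <- matrix(runif(2L * n * n, -spec$jitter_frac, spec$jitter_frac) * pitch,
                  ncol = 2)
    gains <- clamp(rnorm(n * n, 1, spec$gain_sd), 0.5, 1.5)
    structure(list(base_locations = base, locations = base + jit,
                   gains = gains, pitch = pitch, spec = spec),
              class = "phosphene_map")
  })
}

#' @export
print.phosphene_map <- function(x, ...) {
  cat(sprintf("<phosphene_map> %d x %d phosphenes, pitch %.2f px, seed %d\n",
              x$spec$n, x$spec$n, x$pitch, x$spec$seed))
  invisible(x)
}

#' Phosphene activation from a contour mask
#'
#' Each phosphene owns a square receptive window with side equal to the grid
#' pitch, centered on its jittered location and clipped at the display
#' borders. Under `max_pool` a phosphene switches on when any mask pixel in
#' its window is set (the default: contour masks are thin, so mean pooling
#' would extinguish nearly all phosphenes at low resolutions); under
#' `mean_pool` it switches on when the window mean reaches `mean_threshold`.
#'
#' @param map A [build_phosphene_map()] result.
#' @param mask Binary `display_px x display_px` matrix.
#' @param policy `"max_pool"` or `"mean_pool"`.
#' @param mean_threshold Window-mean threshold for `mean_pool` (default 0.5).
#' @return Logical vector of length `n^2`.
#' @export
activate_phosphenes <- function(map, mask, policy = c("max_pool", "mean_pool"),
                                mean_threshold = 0.5) {
  policy <- match.arg(policy)
  d <- map$spec$display_px
  if (!all(dim(mask) == c(d, d)))
    stop_contract("mask must be %d x %d (got %d x %d)", d, d,
                  nrow(mask), ncol(mask))
  half <- map$pitch / 2
  # Pixel p (1-based) has center p - 0.5; the window [c - half, c + half]
  # covers pixels ceil(c - half + 0.5) .. floor(c + half + 0.5), clipped.
  lo_ix <- function(c) clamp(ceiling(c - half + 0.5 - 1e-9), 1, d)
  hi_ix <- function(c) clamp(floor(c + half + 0.5 + 1e-9), 1, d)
  # 2-D prefix sum: S[i+1, j+1] = sum(mask[1:i, 1:j]).
  S <- matrix(0, d + 1L, d + 1L)
  S[2:(d + 1L), 2:(d + 1L)] <- apply(apply(mask > 0, 2, cumsum), 1, cumsum) |> t()
  r1 <- lo_ix(map$locations[, "y"]); r2 <- hi_ix(map$locations[, "y"])
  c1 <- lo_ix(map$locations[, "x"]); c2 <- hi_ix(map$locations[, "x"])
  counts <- S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
  if (policy == "max_pool") counts > 0
  else counts / ((r2 - r1 + 1L) * (c2 - c1 + 1L)) >= mean_threshold
}

#' Render active phosphenes to a display frame
#'
#' Sums per-phosphene Gaussian blobs (`gain * exp(-d^2 / (2 sigma^2))`,
#' truncated at four sigma) for every active phosphene and clips the result
#' to `[0, 1]`.
#'
#' @param map A [build_phosphene_map()] result.
#' @param activations Logical (or 0/1) vector of length `n^2`.
#' @param spec Grid spec; defaults to the spec stored in the map.
#' @return A `phosphene_frame`: list with `activations` and `image`
#'   (`display_px x display_px` matrix in `[0, 1]`).
#' @export
render_phosphenes <- function(map, activations, spec = map$spec) {
  n2 <- spec$n^2
  if (length(activations) != n2)
    stop_contract("`activations` must have length n^2 = %d (got %d)",
                  n2, length(activations))
  act <- as.logical(activations)
  d <- spec$display_px
  img <- matrix(0, d, d)
  sig <- spec$blob_sigma_px
  rad <- ceiling(4 * sig)
  for (k in which(act)) {
    cx <- map$locations[k, "x"]; cy <- map$locations[k, "y"]
    cols <- max(1L, floor(cx + 0.5 - rad)):min(d, ceiling(cx + 0.5 + rad))
    rows <- max(1L, floor(cy + 0.5 - rad)):min(d, ceiling(cy + 0.5 + rad))
    dx2 <- ((cols - 0.5) - cx)^2
    dy2 <- ((rows - 0.5) - cy)^2
    dist2 <- outer(dy2, dx2, `+`)
    blob <- map$gains[k] * exp(-dist2 / (2 * sig^2))
    blob[dist2 > (4 * sig)^2] <- 0
    img[rows, cols] <- img[rows, cols] + blob
  }
  structure(list(activations = act, image = clamp(img, 0, 1), spec = spec),
            class = "phosphene_frame")
}

#' @export
print.phosphene_frame <- function(x, ...) {
  cat(sprintf("<phosphene_frame> %d/%d phosphenes on, %d px display\n",
              sum(x$activations), length(x$activations), x$spec$display_px))
  invisible(x)
}

#' Simulate the phosphene percept of a frame or rendered view
#'
#' Full pipeline: [extract_contours()] -> [activate_phosphenes()] ->
#' [render_phosphenes()]. Pass a prebuilt `map` to keep phosphene jitter and
#' gains constant across the frames of a stream (the default builds the map
#' from `spec`, which is equivalent because maps are frozen by seed).
#'
#' @param x Image frame or `rendered_view`.
#' @param spec A [phosphene_grid_spec()].
#' @param method,params Passed to [extract_contours()].
#' @param policy,mean_threshold Passed to [activate_phosphenes()].
#' @param map Optional prebuilt [build_phosphene_map()] result.
#' @return A `phosphene_frame`.
#' @export
simulate_view <- function(x, spec, method = "ced", params = NULL,
                          policy = "max_pool", mean_threshold = 0.5,
                          map = NULL) {
  map <- map %||% build_phosphene_map(spec)
  mask <- extract_contours(x, method, params)
  act <- activate_phosphenes(map, mask, policy, mean_threshold)
  render_phosphenes(map, act, spec)
}
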