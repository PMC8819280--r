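# Brute-force oracles and small fixture builders, independent of the package
# implementations they check.

# Flood-fill hysteresis: keep candidate pixels (> low) whose 8-connected
# candidate component contains a strong pixel (> high). Explicit BFS.
bf_hysteresis <- function(mag, low, high) {
  nr <- nrow(mag); nc <- ncol(mag)
  cand <- mag > low
  out <- matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  queue <- which(mag > high)
  while (length(queue)) {
    p <- queue[length(queue)]; queue <- queue[-length(queue)]
    if (visited[p] || !cand[p]) next
    visited[p] <- TRUE; out[p] <- TRUE
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
        q <- (j2 - 1L) * nr + i2
        if (cand[q] && !visited[q]) queue <- c(queue, q)
      }
    }
  }
  out + 0L
}

# Exact two-sided signed-rank p by direct enumeration of all 2^n sign
# patterns of the observed absolute ranks (zeros must already be dropped).
bf_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# Per-phosphene window membership by explicit loops (mirrors the documented
# window definition, not the implementation).
bf_activation <- function(map, mask, policy = "max_pool",
                          mean_threshold = 0.5) {
  d <- map$spec$display_px
  half <- map$pitch / 2
  vapply(seq_len(nrow(map$locations)), function(k) {
    cx <- map$locations[k, "x"]; cy <- map$locations[k, "y"]
    rows <- max(1, ceiling(cy - half + 0.5 - 1e-9)):
      min(d, floor(cy + half + 0.5 + 1e-9))
    cols <- max(1, ceiling(cx - half + 0.5 - 1e-9)):
      min(d, floor(cx + half + 0.5 + 1e-9))
    win <- mask[rows, cols]
    if (policy == "max_pool") any(win > 0)
    else mean(win > 0) >= mean_threshold
  }, logical(1))
}

# Per-pixel discontinuity scan (double loop) mirroring the documented
# ground-truth boundary definition: centered second-difference depth test
# along each axis, pairwise 4-neighbor normal-angle test (both marked).
bf_boundaries <- function(view, depth_jump_frac = 0.05,
                          normal_angle_deg = 20) {
  d <- view$depth; nm <- view$normals
  res <- nrow(d)
  cos_thr <- cos(normal_angle_deg * pi / 180)
  out <- matrix(0L, res, res)
  for (i in seq_len(res)) for (j in seq_len(res)) {
    hit <- FALSE
    if (j > 1 && j < res && !anyNA(d[i, (j - 1):(j + 1)]))
      hit <- hit || abs(d[i, j - 1] + d[i, j + 1] - 2 * d[i, j]) >
        depth_jump_frac * d[i, j]
    if (!hit && i > 1 && i < res && !anyNA(d[(i - 1):(i + 1), j]))
      hit <- abs(d[i - 1, j] + d[i + 1, j] - 2 * d[i, j]) >
        depth_jump_frac * d[i, j]
    if (!hit) for (o in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > res || j2 < 1 || j2 > res) next
      if (is.na(d[i, j]) || is.na(d[i2, j2])) next
      if (sum(nm[i, j, ] * nm[i2, j2, ]) < cos_thr) { hit <- TRUE; break }
    }
    if (hit) out[i, j] <- 1L
  }
  out
}

# One small/large box layout helpers.
single_box_layout <- function(size = "large", x = 1.5, y = 8,
                              corridor = corridor_spec()) {
  route_layout(list(obstacle_spec(size, x, y)), corridor = corridor,
               canonical = FALSE)
}

random_candidate_layouts <- function(n, seed) {
  co <- corridor_spec()
  withr::with_seed(seed, {
    out <- list()
    while (length(out) < n) {
      cand <- spvsim:::sample_candidate_layout(co, slot_grid(co),
                                               length(out) + 1L)
      if (is.finite(shortest_path_length(cand, co)))
        out[[length(out) + 1L]] <- cand
    }
    out
  })
}
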