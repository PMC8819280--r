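#' Obstacle slot grid
#'
#' Candidate obstacle positions along the corridor: 13 longitudinal slots at
#' fixed spacing, each offering a left (flush to the left wall), center, or
#' right (flush to the right wall) lateral placement. The exact slot
#' coordinates of the physical course are configuration values; the defaults
#' space 13 slots evenly over the middle of the corridor.
#'
#' @param corridor A [corridor_spec()].
#' @param n_slots Number of longitudinal slots (default 13, one per box).
#' @param y_first,y_spacing First slot position and spacing in meters.
#' @param wall_gap_m Gap between a flush box and the wall (default 0.05).
#' @return List with `y` (slot positions) and `lateral` (option labels).
#' @export
slot_grid <- function(corridor = corridor_spec(), n_slots = 13L,
                      y_first = 2.0, y_spacing = 1.4, wall_gap_m = 0.05) {
  y <- y_first + y_spacing * (seq_len(n_slots) - 1L)
  if (max(y) > corridor$length_m)
    stop_contract("slot grid extends past the corridor end")
  list(y = y, lateral = c("left", "center", "right"), wall_gap_m = wall_gap_m)
}

slot_x_center <- function(lateral, size_class, corridor, wall_gap_m) {
  half <- .obstacle_dims[[size_class]][["x"]] / 2
  switch(lateral,
         left = wall_gap_m + half,
         center = corridor$width_m / 2,
         right = corridor$width_m - wall_gap_m - half)
}

#' Generate difficulty-matched route layouts
#'
#' Samples random obstacle placements on the slot grid (7 small + 6 large
#' boxes; random slot-to-size assignment and lateral positions), keeps
#' `n_routes` passable layouts whose shortest-path lengths all lie within
#' `tolerance` of their median, and appends the mirrored version of each.
#' Deterministic given `seed`.
#'
#' @param n_routes Number of base routes (default 7; the mirrored versions
#'   double the returned count).
#' @param corridor A [corridor_spec()].
#' @param tolerance Relative difficulty tolerance: every selected length
#'   must satisfy `|len - median| <= tolerance * median` (default 0.02).
#' @param seed Integer seed.
#' @param agent_radius_m Inflation radius for path-length evaluation.
#' @param slots Slot configuration from [slot_grid()].
#' @param max_attempts Candidate budget before the search fails.
#' @return List of `2 * n_routes` [route_layout()] objects (bases first,
#'   then their mirrors), with shortest-path lengths attached as attribute
#'   `"lengths"` (for the base layouts).
#' @export
generate_route_layouts <- function(n_routes = 7L, corridor = corridor_spec(),
                                   tolerance = 0.02, seed = 1L,
                                   agent_radius_m = 0.30,
                                   slots = slot_grid(corridor),
                                   max_attempts = 400L) {
  if (n_routes < 1L) stop_contract("`n_routes` must be >= 1")
  run_seeded(seed, {
    pool <- list(); lens <- numeric(0); attempts <- 0L
    repeat {
      batch <- max(n_routes * 3L, 12L)
      for (i in seq_len(batch)) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop_contract(paste0(
            "route search failed: no %d layouts within tolerance %.3f after ",
            "%d candidate layouts"), n_routes, tolerance, max_attempts)
        cand <- sample_candidate_layout(corridor, slots,
                                        layout_id = length(pool) + 1L)
        len <- shortest_path_length(cand, corridor, agent_radius_m)
        if (!is.finite(len)) next
        pool[[length(pool) + 1L]] <- cand
        lens <- c(lens, len)
      }
      sel <- select_matched(lens, n_routes, tolerance)
      if (!is.null(sel)) break
    }
    base <- pool[sel]
    for (i in seq_along(base)) base[[i]]$layout_id <- i
    mirrored <- lapply(base, mirror_layout, corridor = corridor)
    out <- c(base, mirrored)
    attr(out, "lengths") <- lens[sel]
    out
  })
}

sample_candidate_layout <- function(corridor, slots, layout_id) {
  n_slots <- length(slots$y)
  sizes <- sample(c(rep("small", 7L), rep("large", 6L)))[seq_len(min(13L, n_slots))]
  lateral <- sample(slots$lateral, n_slots, replace = TRUE)
  obs <- lapply(seq_len(n_slots), function(k)
    obstacle_spec(sizes[k],
                  slot_x_center(lateral[k], sizes[k], corridor,
                                slots$wall_gap_m),
                  slots$y[k]))
  route_layout(obs, layout_id = layout_id, corridor = corridor,
               canonical = n_slots == 13L)
}

# Pick n indices whose lengths all lie within tol of their median, or NULL.
# Among valid windows, prefer the one whose difficulty is most typical of the
# candidate pool (window median closest to the pool median), so selection
# does not collapse onto the easiest near-straight routes.
select_matched <- function(lens, n, tol) {
  if (length(lens) < n) return(NULL)
  ord <- order(lens)
  pool_med <- median(lens)
  best <- NULL; best_off <- Inf
  for (s in seq_len(length(lens) - n + 1L)) {
    win <- ord[s:(s + n - 1L)]
    med <- median(lens[win])
    if (all(abs(lens[win] - med) <= tol * med + 1e-12)) {
      off <- abs(med - pool_med)
      if (off < best_off) { best <- win; best_off <- off }
    }
  }
  best
}

#' Camera poses along a walked route
#'
#' Produces a stream of camera poses following the shortest collision-free
#' path through a layout at constant speed, with uniform arc-length spacing
#' `speed_mps / frame_rate_hz` and yaw facing along the path tangent. The
#' first and last poses sit at the path's endpoints.
#'
#' @inheritParams shortest_path
#' @param speed_mps Walking speed in m/s (> 0).
#' @param frame_rate_hz Frame rate in Hz (> 0).
#' @param eye_height_m Camera height above the floor (default 1.6).
#' @param fov_deg Field of view for the generated poses.
#' @return List of [camera_pose()] objects.
#' @export
walkthrough <- function(layout, corridor = corridor_spec(), speed_mps = 1,
                        frame_rate_hz = 10, agent_radius_m = 0.30,
                        eye_height_m = 1.6, fov_deg = 35) {
  check_number(speed_mps, "speed_mps", 0, strict_lower = TRUE)
  check_number(frame_rate_hz, "frame_rate_hz", 0, strict_lower = TRUE)
  sp <- shortest_path(layout, corridor, agent_radius_m)
  if (sp$blocked) stop_contract("layout is blocked; no walkable path exists")
  path <- sp$path
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  keep <- seg_len > 1e-12
  seg <- seg[keep, , drop = FALSE]; seg_len <- seg_len[keep]
  path <- path[c(TRUE, keep), , drop = FALSE]
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  step <- speed_mps / frame_rate_hz
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  lapply(s, function(si) {
    k <- max(1L, min(findInterval(si, cum, rightmost.closed = TRUE),
                     nrow(seg)))
    frac <- (si - cum[k]) / seg_len[k]
    pos <- path[k, ] + frac * seg[k, ]
    yaw <- atan2(seg[k, 1], seg[k, 2]) * 180 / pi
    camera_pose(c(pos[1], pos[2], eye_height_m), yaw = yaw, pitch = 0,
                fov_deg = fov_deg)
  })
}
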