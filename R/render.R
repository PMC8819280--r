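#' Camera pose
#'
#' Pinhole camera pose inside the corridor. Yaw is measured about the `z`
#' axis with `yaw = 0` facing down the corridor (+y) and positive yaw turning
#' toward +x; pitch is positive upward. The field of view defaults to 35
#' degrees so the rendered frame spans the same visual angle as the phosphene
#' display.
#'
#' @param position Numeric length-3 `(x, y, z)` in meters.
#' @param yaw,pitch Angles in degrees.
#' @param fov_deg Horizontal (= vertical) field of view in degrees, in
#'   (0, 180).
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(position, yaw = 0, pitch = 0, fov_deg = 35) {
  if (length(position) != 3L || !is.numeric(position))
    stop_contract("`position` must be a numeric (x, y, z)")
  check_number(fov_deg, "fov_deg", 0, 180, strict_lower = TRUE)
  if (fov_deg >= 180) stop_contract("`fov_deg` must be < 180")
  structure(list(position = as.numeric(position), yaw = yaw, pitch = pitch,
                 fov_deg = fov_deg),
            class = "camera_pose")
}

pose_inside <- function(pose, corridor) {
  p <- pose$position
  p[1] >= 0 && p[1] <= corridor$width_m &&
    p[2] >= 0 && p[2] <= corridor$length_m &&
    p[3] >= 0 && p[3] <= corridor$wall_height_m
}

# Flat per-surface reflectance of the plain condition: dark floor, light
# ceiling, mid-gray walls, boxes lit face-by-face. Box faces cycle through a
# well-separated shade palette (directional lighting makes the faces of one
# box differ, and individual boxes differ), so every visible surface
# boundary carries a luminance step.
.surface_values <- c(floor = 0.25, ceiling = 0.95, wall_left = 0.52,
                     wall_right = 0.58, wall_end = 0.40, wall_start = 0.52)
.box_palette <- c(0.10, 0.72, 0.85, 0.98)
.box_face_value <- function(b, f) .box_palette[(2L * b + f) %% 4L + 1L]

#' Render a corridor view
#'
#' Ray-casts a pinhole view of the corridor (floor, ceiling, walls) and the
#' layout's box obstacles, producing an RGB raster together with ground-truth
#' depth, per-pixel unit surface normals, a surface-identity map and a
#' ground-truth surface-boundary mask (see [ground_truth_boundaries()]).
#' Depth is planar depth: distance along the camera's forward axis, so a
#' frontal wall at distance `d` has a constant depth map of `d`.
#'
#' In the `"complex"` corridor condition, procedural stripe textures with
#' per-surface phase are multiplied into the surface reflectance of the
#' floor, walls and box faces; geometry, depth, normals and the ground-truth
#' boundary mask are unaffected by texture.
#'
#' @param corridor A [corridor_spec()].
#' @param layout A [route_layout()] (may be non-canonical or empty).
#' @param pose A [camera_pose()]; must lie inside the corridor.
#' @param res Raster side in pixels (default 480).
#' @return An object of class `rendered_view`: list with `rgb`
#'   (`res x res x 3` in `[0, 1]`), `depth` (meters), `normals`
#'   (`res x res x 3`), `surface_id` (integer matrix), `gt_boundary` (binary
#'   matrix) and the inputs.
#' @export
render_view <- function(corridor, layout = NULL, pose, res = 480L) {
  stopifnot(inherits(corridor, "corridor_spec"), inherits(pose, "camera_pose"))
  if (!pose_inside(pose, corridor))
    stop_contract("invalid pose: camera position (%.2f, %.2f, %.2f) outside corridor",
                  pose$position[1], pose$position[2], pose$position[3])
  res <- as.integer(res)
  obstacles <- if (is.null(layout)) list() else layout$obstacles

  f_px <- (res / 2) / tan(pose$fov_deg / 2 * pi / 180)
  yaw <- pose$yaw * pi / 180
  pitch <- pose$pitch * pi / 180
  fwd <- c(sin(yaw) * cos(pitch), cos(yaw) * cos(pitch), sin(pitch))
  right <- c(cos(yaw), -sin(yaw), 0)
  up <- c(-sin(yaw) * sin(pitch), -cos(yaw) * sin(pitch), cos(pitch))

  # Pixel centers at half-integers, origin top-left, rows downward.
  jj <- matrix(rep(seq_len(res), each = res), res, res)   # column index
  ii <- matrix(rep(seq_len(res), times = res), res, res)  # row index
  u <- (as.vector(jj) - 0.5 - res / 2) / f_px
  v <- (res / 2 - (as.vector(ii) - 0.5)) / f_px
  # Unnormalized ray direction with d . fwd = 1: ray parameter t is planar depth.
  dx <- fwd[1] + u * right[1] + v * up[1]
  dy <- fwd[2] + u * right[2] + v * up[2]
  dz <- fwd[3] + u * right[3] + v * up[3]
  p <- pose$position
  n_pix <- res * res

  depth <- rep(Inf, n_pix)
  sid <- integer(n_pix)           # 0 = miss
  eps <- 1e-9

  # Room planes: axis (1=x, 2=y, 3=z), plane value, inward normal.
  W <- corridor$width_m; L <- corridor$length_m; H <- corridor$wall_height_m
  planes <- list(
    floor      = list(axis = 3, value = 0, normal = c(0, 0, 1)),
    ceiling    = list(axis = 3, value = H, normal = c(0, 0, -1)),
    wall_left  = list(axis = 1, value = 0, normal = c(1, 0, 0)),
    wall_right = list(axis = 1, value = W, normal = c(-1, 0, 0)),
    wall_end   = list(axis = 2, value = L, normal = c(0, -1, 0)),
    wall_start = list(axis = 2, value = 0, normal = c(0, 1, 0)))
  dmat <- cbind(dx, dy, dz)
  for (k in seq_along(planes)) {
    pl <- planes[[k]]
    da <- dmat[, pl$axis]
    t <- (pl$value - p[pl$axis]) / da
    ok <- is.finite(t) & t > eps & t < depth
    if (any(ok)) {
      hx <- p[1] + t[ok] * dx[ok]; hy <- p[2] + t[ok] * dy[ok]
      hz <- p[3] + t[ok] * dz[ok]
      inb <- hx >= -eps & hx <= W + eps & hy >= -eps & hy <= L + eps &
        hz >= -eps & hz <= H + eps
      idx <- which(ok)[inb]
      depth[idx] <- t[ok][inb]
      sid[idx] <- k
    }
  }

  # Boxes via the slab method; face id from the entering slab.
  for (b in seq_along(obstacles)) {
    ob <- obstacles[[b]]
    lo <- c(ob$xmin, ob$ymin, 0); hi <- c(ob$xmax, ob$ymax, ob$height_m)
    t1 <- (lo[1] - p[1]) / dx; t2 <- (hi[1] - p[1]) / dx
    txmin <- pmin(t1, t2); txmax <- pmax(t1, t2)
    t1 <- (lo[2] - p[2]) / dy; t2 <- (hi[2] - p[2]) / dy
    tymin <- pmin(t1, t2); tymax <- pmax(t1, t2)
    t1 <- (lo[3] - p[3]) / dz; t2 <- (hi[3] - p[3]) / dz
    tzmin <- pmin(t1, t2); tzmax <- pmax(t1, t2)
    tn <- pmax(txmin, tymin, tzmin)
    tf <- pmin(txmax, tymax, tzmax)
    ok <- is.finite(tn) & tn <= tf & tn > eps & tn < depth
    if (!any(ok)) next
    face <- integer(sum(ok))  # 1 x-, 2 x+, 3 y-, 4 y+, 5 top
    fx <- tn[ok] == txmin[ok]; fy <- !fx & tn[ok] == tymin[ok]
    fz <- !fx & !fy
    face[fx] <- ifelse(dx[ok][fx] > 0, 1L, 2L)
    face[fy] <- ifelse(dy[ok][fy] > 0, 3L, 4L)
    face[fz] <- 5L
    idx <- which(ok)
    depth[idx] <- tn[ok]
    sid[idx] <- 6L + (b - 1L) * 5L + face
  }

  # Per-surface normals and shading values.
  n_surf <- 6L + 5L * length(obstacles)
  normals_tab <- matrix(0, n_surf, 3)
  kind <- character(n_surf)
  for (k in seq_along(planes)) {
    normals_tab[k, ] <- planes[[k]]$normal
    kind[k] <- names(planes)[k]
  }
  face_normals <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                        c(0, 0, 1))
  face_kind <- c("box_xneg", "box_xpos", "box_yneg", "box_ypos", "box_top")
  for (b in seq_along(obstacles)) for (f in 1:5) {
    normals_tab[6L + (b - 1L) * 5L + f, ] <- face_normals[f, ]
    kind[6L + (b - 1L) * 5L + f] <- face_kind[f]
  }
  base_val <- numeric(n_surf)
  base_val[1:6] <- .surface_values[kind[1:6]]
  if (length(obstacles))
    for (b in seq_along(obstacles)) for (f in 1:5)
      base_val[6L + (b - 1L) * 5L + f] <- .box_face_value(b, f)

  hitx <- p[1] + depth * dx; hity <- p[2] + depth * dy; hitz <- p[3] + depth * dz
  val <- ifelse(sid > 0L, base_val[sid], 0)

  if (corridor$complexity == "complex") {
    tp <- corridor$texture_params
    # Surface-local coordinate the stripes run across; per-surface phase.
    uu <- numeric(n_pix); vv <- numeric(n_pix)
    horiz <- kind %in% c("floor", "ceiling", "box_top")
    h <- sid > 0L & horiz[pmax(sid, 1L)]
    w <- sid > 0L & !horiz[pmax(sid, 1L)]
    uu[h] <- hitx[h]; vv[h] <- hity[h]
    uu[w] <- ifelse(abs(normals_tab[sid[w], 1]) > 0.5, hity[w], hitx[w])
    vv[w] <- hitz[w]
    phase <- ((sid * 2654435761 + tp$seed * 97) %% 1000) / 1000 * tp$stripe_period_m
    along_u <- (sid %% 2L) == 0L
    coord <- ifelse(along_u, uu, vv) + phase
    stripe <- sign(sin(2 * pi * coord / tp$stripe_period_m))
    stripe[stripe == 0] <- 1
    # Wallpaper/tape goes on the floor, the walls and the boxes; not the ceiling.
    textured <- sid > 0L & kind[pmax(sid, 1L)] != "ceiling"
    val <- ifelse(textured, clamp(val * (1 + tp$contrast * stripe), 0, 1), val)
  }

  rgb <- array(0, c(res, res, 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(clamp(val, 0, 1), res, res)

  nmap <- array(0, c(res, res, 3))
  for (ch in 1:3)
    nmap[, , ch] <- matrix(ifelse(sid > 0L, normals_tab[pmax(sid, 1L), ch], 0),
                           res, res)

  view <- structure(list(
    rgb = rgb,
    depth = matrix(ifelse(is.finite(depth), depth, NA_real_), res, res),
    normals = nmap,
    surface_id = matrix(sid, res, res),
    res = res, pose = pose, corridor = corridor, layout = layout),
    class = "rendered_view")
  view$gt_boundary <- ground_truth_boundaries(view)
  view
}

#' @export
print.rendered_view <- function(x, ...) {
  cat(sprintf("<rendered_view> %dx%d px, %s corridor, depth %.2f-%.2f m\n",
              x$res, x$res, x$corridor$complexity,
              min(x$depth, na.rm = TRUE), max(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' Ground-truth surface boundaries from depth and normals
#'
#' Marks a pixel as a surface boundary when its depth profile is
#' discontinuous along either image axis, or when the angle between the unit
#' normals of 4-neighbors exceeds a threshold. The depth criterion is a
#' centered second-difference test, `|d(p-1) + d(p+1) - 2 d(p)| >
#' depth_jump_frac * d(p)` along rows or columns: a genuine occlusion step
#' trips it at the step magnitude, while the smooth (but at grazing angles
#' steep) perspective depth gradient within a planar surface does not. For
#' the normal criterion both pixels of an offending pair are marked. The
#' mask depends only on geometry, never on textures or shading; it serves as
#' the idealized output of a surface-boundary predictor.
#'
#' @param view A [render_view()] result with `depth` and `normals`.
#' @param depth_jump_frac Relative depth-discontinuity threshold
#'   (default 0.05).
#' @param normal_angle_deg Angular threshold between neighbor normals in
#'   degrees (default 20).
#' @return Binary matrix (`res x res`, values 0/1) of class `contour_mask`.
#' @export
ground_truth_boundaries <- function(view, depth_jump_frac = 0.05,
                                    normal_angle_deg = 20) {
  if (is.null(view$depth) || is.null(view$normals))
    stop_contract("view lacks depth/normal channels")
  d <- view$depth
  cos_thr <- cos(normal_angle_deg * pi / 180)
  res <- nrow(d)
  mask <- matrix(FALSE, res, res)
  # Depth: centered second difference along each axis.
  mid <- 2:(res - 1)
  h <- abs(d[, mid - 1] + d[, mid + 1] - 2 * d[, mid]) >
    depth_jump_frac * d[, mid]
  mask[, mid] <- mask[, mid] | (!is.na(h) & h)
  v <- abs(d[mid - 1, ] + d[mid + 1, ] - 2 * d[mid, ]) >
    depth_jump_frac * d[mid, ]
  mask[mid, ] <- mask[mid, ] | (!is.na(v) & v)
  # Normals: pairwise angle between 4-neighbors; mark both pixels.
  ndot <- function(ar, ac, br, bc) {
    view$normals[ar, ac, 1] * view$normals[br, bc, 1] +
      view$normals[ar, ac, 2] * view$normals[br, bc, 2] +
      view$normals[ar, ac, 3] * view$normals[br, bc, 3]
  }
  ok <- !is.na(d)
  bh <- ndot(1:res, 1:(res - 1), 1:res, 2:res) < cos_thr &
    ok[, 1:(res - 1)] & ok[, 2:res]
  mask[, 1:(res - 1)] <- mask[, 1:(res - 1)] | bh
  mask[, 2:res] <- mask[, 2:res] | bh
  bv <- ndot(1:(res - 1), 1:res, 2:res, 1:res) < cos_thr &
    ok[1:(res - 1), ] & ok[2:res, ]
  mask[1:(res - 1), ] <- mask[1:(res - 1), ] | bv
  mask[2:res, ] <- mask[2:res, ] | bv
  structure(mask + 0L, class = c("contour_mask", "matrix"))
}
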