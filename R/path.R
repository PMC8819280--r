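# Shortest collision-free paths through the obstacle course.
#
# Free space model: the walking agent is a disk approximated by a square of
# half-width `agent_radius_m`; obstacle footprints are inflated axis-aligned
# by that radius (Minkowski sum with the square) and the usable corridor
# narrows to x in [r, width - r]. The start is the corridor entrance midline
# (width/2, 0); the goal is the line y = length. Both the visibility-graph
# planner and the grid oracle share this free-space definition and differ
# only in the path metric.

inflated_rects <- function(obstacles, r) {
  if (length(obstacles) == 0L)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("xmin", "xmax", "ymin", "ymax"))))
  t(vapply(obstacles, function(ob)
    c(ob$xmin - r, ob$xmax + r, ob$ymin - r, ob$ymax + r), numeric(4))) |>
    `colnames<-`(c("xmin", "xmax", "ymin", "ymax"))
}

# TRUE where (px, py) lies strictly inside any rectangle.
points_in_rects <- function(px, py, rects, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  for (k in seq_len(nrow(rects)))
    inside <- inside |
      (px > rects[k, "xmin"] + eps & px < rects[k, "xmax"] - eps &
       py > rects[k, "ymin"] + eps & py < rects[k, "ymax"] - eps)
  inside
}

# TRUE if the open segment (p, q) intersects the interior of any rectangle
# (boundary grazing allowed).
segment_blocked <- function(p, q, rects, eps = 1e-9) {
  d <- q - p
  for (k in seq_len(nrow(rects))) {
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (ax in 1:2) {
      lo <- rects[k, if (ax == 1) "xmin" else "ymin"] + eps
      hi <- rects[k, if (ax == 1) "xmax" else "ymax"] - eps
      if (abs(d[ax]) < 1e-15) {
        if (p[ax] <= lo || p[ax] >= hi) { ok <- FALSE; break }
      } else {
        ta <- (lo - p[ax]) / d[ax]; tb <- (hi - p[ax]) / d[ax]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        if (t0 >= t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 - t0 > 1e-12) return(TRUE)
  }
  FALSE
}

#' Shortest collision-free path through a layout
#'
#' Computes the shortest 2-D path from the corridor entrance midline to the
#' far goal line around the layout's obstacles, using a visibility graph over
#' the corners of the inflated obstacle footprints with Dijkstra search
#' (via igraph). The final leg reaches the goal line perpendicularly, as the
#' taut-path optimality condition requires.
#'
#' @param layout A [route_layout()] (or a bare list of [obstacle_spec()]).
#' @param corridor A [corridor_spec()].
#' @param agent_radius_m Footprint inflation radius in meters (default 0.30,
#'   roughly a shoulder half-width).
#' @return `shortest_path()` returns a list with `length_m` (`Inf` when the
#'   corridor is blocked), `path` (two-column matrix of way-points, `NULL`
#'   when blocked) and `blocked`. `shortest_path_length()` returns just the
#'   length.
#' @export
shortest_path <- function(layout, corridor = corridor_spec(),
                          agent_radius_m = 0.30) {
  obstacles <- if (inherits(layout, "route_layout")) layout$obstacles else layout
  r <- agent_radius_m
  W <- corridor$width_m; L <- corridor$length_m
  band <- c(r, W - r)
  rects <- inflated_rects(obstacles, r)
  start <- c(W / 2, 0)

  # Nodes: start + inflated corners clamped to the usable band, excluding
  # corners buried inside another inflated rectangle.
  corners <- matrix(numeric(0), 0, 2)
  if (nrow(rects) > 0) {
    cx <- as.vector(t(rects[, c("xmin", "xmax", "xmin", "xmax"), drop = FALSE]))
    cy <- as.vector(t(rects[, c("ymin", "ymin", "ymax", "ymax"), drop = FALSE]))
    keep <- cx >= band[1] - 1e-9 & cx <= band[2] + 1e-9 &
      cy >= 0 & cy <= L & !points_in_rects(cx, cy, rects)
    corners <- cbind(clamp(cx[keep], band[1], band[2]), cy[keep])
  }
  nodes <- rbind(start, corners)
  if (points_in_rects(start[1], start[2], rects))
    return(list(length_m = Inf, path = NULL, blocked = TRUE))

  n <- nrow(nodes)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (!segment_blocked(nodes[i, ], nodes[j, ], rects)) {
        from <- c(from, i); to <- c(to, j)
        wt <- c(wt, sqrt(sum((nodes[i, ] - nodes[j, ])^2)))
      }
    }
  # Perpendicular goal-line edges where the vertical ray to y = L is free.
  goal_id <- n + 1L
  for (i in 1:n) {
    if (!segment_blocked(nodes[i, ], c(nodes[i, 1], L), rects)) {
      from <- c(from, i); to <- c(to, goal_id)
      wt <- c(wt, L - nodes[i, 2])
    }
  }
  if (!any(to == goal_id))
    return(list(length_m = Inf, path = NULL, blocked = TRUE))

  g <- igraph::make_empty_graph(n = goal_id, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  dist <- igraph::distances(g, v = 1, to = goal_id)[1, 1]
  if (!is.finite(dist))
    return(list(length_m = Inf, path = NULL, blocked = TRUE))
  vp <- igraph::shortest_paths(g, from = 1, to = goal_id)$vpath[[1]]
  ids <- as.integer(vp)
  path <- nodes[ids[ids <= n], , drop = FALSE]
  path <- rbind(path, c(path[nrow(path), 1], L))
  dimnames(path) <- list(NULL, c("x", "y"))
  list(length_m = dist, path = path, blocked = FALSE)
}

#' @rdname shortest_path
#' @export
shortest_path_length <- function(layout, corridor = corridor_spec(),
                                 agent_radius_m = 0.30) {
  shortest_path(layout, corridor, agent_radius_m)$length_m
}

#' Grid-Dijkstra path length (brute-force checker)
#'
#' Independent re-computation of the shortest path length on a fine regular
#' grid (default 5 cm). The lattice uses an extended move neighbourhood (all
#' coprime offsets with coordinates up to `max_offset`), which bounds the
#' metric overestimate of the lattice relative to the Euclidean shortest
#' path below about 1%. Intended as a validation oracle for
#' [shortest_path_length()], not for production use.
#'
#' @inheritParams shortest_path
#' @param cell_m Grid spacing in meters (default 0.05).
#' @param max_offset Largest move coordinate in cells (default 4).
#' @return Path length in meters (`Inf` when blocked).
#' @export
grid_path_length <- function(layout, corridor = corridor_spec(),
                             agent_radius_m = 0.30, cell_m = 0.05,
                             max_offset = 4L) {
  obstacles <- if (inherits(layout, "route_layout")) layout$obstacles else layout
  r <- agent_radius_m
  W <- corridor$width_m; L <- corridor$length_m
  rects <- inflated_rects(obstacles, r)
  xs <- seq(r, W - r, by = cell_m)
  if (abs(xs[length(xs)] - (W - r)) > 1e-9) xs <- c(xs, W - r)
  ys <- seq(0, L, by = cell_m)
  if (abs(ys[length(ys)] - L) > 1e-9) ys <- c(ys, L)
  nx <- length(xs); ny <- length(ys)

  px <- rep(xs, each = ny); py <- rep(ys, times = nx)
  free <- !points_in_rects(px, py, rects)
  node_id <- function(ix, iy) (ix - 1L) * ny + iy

  # Coprime first-octant directions up to max_offset, expanded to the half
  # plane (undirected edges added once).
  dirs <- list()
  for (a in 0:max_offset) for (b in 0:max_offset) {
    if (a == 0 && b == 0) next
    if (max(a, b) > max_offset) next
    if (a > 0 && b > 0 && .gcd(a, b) != 1) next
    if (a == 0 && b != 1) next
    if (b == 0 && a != 1) next
    dirs[[length(dirs) + 1L]] <- c(a, b)
  }
  offs <- do.call(rbind, dirs)
  offs <- rbind(offs, cbind(-offs[offs[, 2] > 0, 1], offs[offs[, 2] > 0, 2]))

  from <- list(); to <- list(); wt <- list()
  for (k in seq_len(nrow(offs))) {
    a <- offs[k, 1]; b <- offs[k, 2]
    ix_rng <- seq(max(1L, 1L - a), min(nx, nx - a))
    iy_rng <- seq(max(1L, 1L - b), min(ny, ny - b))
    if (!length(ix_rng) || !length(iy_rng)) next
    ix <- rep(ix_rng, each = length(iy_rng))
    iy <- rep(iy_rng, times = length(ix_rng))
    v1 <- node_id(ix, iy); v2 <- node_id(ix + a, iy + b)
    ok <- free[v1] & free[v2]
    if (!any(ok)) next
    ix <- ix[ok]; iy <- iy[ok]; v1 <- v1[ok]; v2 <- v2[ok]
    m <- max(abs(a), abs(b))
    if (m > 1L && nrow(rects) > 0) {
      good <- rep(TRUE, length(v1))
      for (s in seq_len(m - 1L)) {
        fx <- xs[ix] + s / m * a * cell_m
        fy <- ys[iy] + s / m * b * cell_m
        good <- good & !points_in_rects(fx, fy, rects)
        if (!any(good)) break
      }
      v1 <- v1[good]; v2 <- v2[good]
    }
    if (!length(v1)) next
    from[[length(from) + 1L]] <- v1
    to[[length(to) + 1L]] <- v2
    wt[[length(wt) + 1L]] <- rep(cell_m * sqrt(a^2 + b^2), length(v1))
  }
  from <- unlist(from); to <- unlist(to); wt <- unlist(wt)

  # Start node: nearest grid node to the entrance midline; goal: any node on
  # the last row (y = L).
  six <- which.min(abs(xs - W / 2)); start <- node_id(six, 1L)
  if (!free[start]) return(Inf)
  goal_nodes <- node_id(seq_len(nx), ny)
  goal_nodes <- goal_nodes[free[goal_nodes]]
  if (!length(goal_nodes) || !length(from)) return(Inf)

  g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  d <- igraph::distances(g, v = start, to = goal_nodes)
  min(d)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
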