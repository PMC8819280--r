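#' Corridor specification
#'
#' Describes the indoor obstacle-course environment: a straight corridor with
#' a floor, a ceiling, two side walls and an end wall. The coordinate frame
#' has `x` across the corridor width, `y` along its length (the walking
#' direction) and `z` up; all units are meters. The `complexity` flag selects
#' between a `"plain"` variant (uniform albedo per surface) and a `"complex"`
#' variant where procedural stripe/patch textures (emulating wallpaper and
#' tape) are applied to the floor, the walls and the obstacle faces.
#'
#' @param width_m Corridor width in meters (default 3).
#' @param length_m Corridor length in meters (default 22).
#' @param wall_height_m Ceiling height in meters (default 2.5).
#' @param complexity `"plain"` or `"complex"`.
#' @param texture_params List of procedural texture settings used only in the
#'   complex condition: `stripe_period_m` (spatial period of the stripe
#'   pattern), `contrast` (multiplicative albedo modulation depth in
#'   `[0, 1)`), and `seed` (per-surface pattern phase seed).
#' @return An object of class `corridor_spec`.
#' @export
corridor_spec <- function(width_m = 3, length_m = 22, wall_height_m = 2.5,
                          complexity = c("plain", "complex"),
                          texture_params = list(stripe_period_m = 0.5,
                                                contrast = 0.35,
                                                seed = 1L)) {
  complexity <- match.arg(complexity)
  check_number(width_m, "width_m", 0, strict_lower = TRUE)
  check_number(length_m, "length_m", 0, strict_lower = TRUE)
  check_number(wall_height_m, "wall_height_m", 0, strict_lower = TRUE)
  tp <- utils::modifyList(list(stripe_period_m = 0.5, contrast = 0.35,
                               seed = 1L), texture_params)
  check_number(tp$contrast, "texture_params$contrast", 0, 1)
  structure(list(width_m = width_m, length_m = length_m,
                 wall_height_m = wall_height_m, complexity = complexity,
                 texture_params = tp),
            class = "corridor_spec")
}

#' @export
print.corridor_spec <- function(x, ...) {
  cat(sprintf("<corridor_spec> %.1f x %.1f x %.1f m, %s\n",
              x$width_m, x$length_m, x$wall_height_m, x$complexity))
  invisible(x)
}

# Box dimensions (x across corridor, y along corridor, z up), meters.
.obstacle_dims <- list(small = c(x = 0.50, y = 0.30, z = 0.90),
                       large = c(x = 0.75, y = 0.30, z = 1.80))

#' Obstacle (cardboard box) specification
#'
#' One axis-aligned box obstacle. Two size classes are supported: `"small"`
#' (0.30 x 0.50 x 0.90 m) and `"large"` (0.30 x 0.75 x 1.80 m), stated as
#' depth (along corridor) x width (across corridor) x height.
#'
#' @param size_class `"small"` or `"large"`.
#' @param x_center,y_center Footprint center in corridor coordinates (m).
#' @return An object of class `obstacle_spec` with the footprint rectangle
#'   (`xmin`, `xmax`, `ymin`, `ymax`) and `height_m`.
#' @export
obstacle_spec <- function(size_class = c("small", "large"),
                          x_center, y_center) {
  size_class <- match.arg(size_class)
  check_number(x_center, "x_center")
  check_number(y_center, "y_center")
  d <- .obstacle_dims[[size_class]]
  structure(list(size_class = size_class,
                 xmin = x_center - d[["x"]] / 2, xmax = x_center + d[["x"]] / 2,
                 ymin = y_center - d[["y"]] / 2, ymax = y_center + d[["y"]] / 2,
                 height_m = d[["z"]]),
            class = "obstacle_spec")
}

obstacle_inside <- function(ob, corridor) {
  ob$xmin >= 0 && ob$xmax <= corridor$width_m &&
    ob$ymin >= 0 && ob$ymax <= corridor$length_m
}

obstacles_overlap <- function(a, b) {
  a$xmin < b$xmax && b$xmin < a$xmax && a$ymin < b$ymax && b$ymin < a$ymax
}

#' Route layout
#'
#' An arrangement of box obstacles along the corridor. The canonical study
#' layout contains exactly seven small and six large boxes with
#' non-overlapping footprints; set `canonical = FALSE` to build reduced
#' layouts (e.g. a single box) for testing and demonstration.
#'
#' @param obstacles List of [obstacle_spec()] objects.
#' @param layout_id Identifier (integer or string).
#' @param mirrored Logical; whether this layout is the mirror (left-right
#'   flip) of a base layout.
#' @param corridor A [corridor_spec()]; footprints must lie inside it.
#' @param canonical Enforce the 7 small + 6 large composition.
#' @return An object of class `route_layout`.
#' @export
route_layout <- function(obstacles, layout_id = "layout",
                         mirrored = FALSE, corridor = corridor_spec(),
                         canonical = TRUE) {
  if (!all(vapply(obstacles, inherits, logical(1), "obstacle_spec")))
    stop_contract("`obstacles` must be a list of obstacle_spec objects")
  if (canonical) {
    sizes <- vapply(obstacles, `[[`, character(1), "size_class")
    if (sum(sizes == "small") != 7L || sum(sizes == "large") != 6L)
      stop_contract("canonical layout requires 7 small + 6 large obstacles, got %d small + %d large",
                    sum(sizes == "small"), sum(sizes == "large"))
  }
  for (ob in obstacles)
    if (!obstacle_inside(ob, corridor))
      stop_contract("obstacle footprint [%.2f,%.2f]x[%.2f,%.2f] outside corridor",
                    ob$xmin, ob$xmax, ob$ymin, ob$ymax)
  n <- length(obstacles)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (obstacles_overlap(obstacles[[i]], obstacles[[j]]))
        stop_contract("obstacles %d and %d have overlapping footprints", i, j)
  structure(list(obstacles = obstacles, layout_id = layout_id,
                 mirrored = isTRUE(mirrored)),
            class = "route_layout")
}

#' @export
print.route_layout <- function(x, ...) {
  sizes <- vapply(x$obstacles, `[[`, character(1), "size_class")
  cat(sprintf("<route_layout '%s'%s> %d obstacles (%d small, %d large)\n",
              x$layout_id, if (x$mirrored) " mirrored" else "",
              length(x$obstacles), sum(sizes == "small"),
              sum(sizes == "large")))
  invisible(x)
}

#' Mirror a route layout across the corridor midline
#'
#' Reflects every obstacle footprint in `x = width/2` and toggles the
#' `mirrored` flag. Mirroring preserves shortest-path difficulty exactly.
#'
#' @param layout A [route_layout()].
#' @param corridor The corridor the layout lives in.
#' @return The mirrored `route_layout`.
#' @export
mirror_layout <- function(layout, corridor = corridor_spec()) {
  w <- corridor$width_m
  obs <- lapply(layout$obstacles, function(ob) {
    xc <- w - (ob$xmin + ob$xmax) / 2
    obstacle_spec(ob$size_class, xc, (ob$ymin + ob$ymax) / 2)
  })
  route_layout(obs, layout_id = layout$layout_id,
               mirrored = !layout$mirrored, corridor = corridor,
               canonical = FALSE)
}

#' Export / import route layouts as JSON
#'
#' @param layouts A list of [route_layout()] objects.
#' @param path File path.
#' @return `write_layouts_json` returns `path` invisibly;
#'   `read_layouts_json` returns a list of `route_layout` objects.
#' @export
write_layouts_json <- function(layouts, path) {
  as_rec <- function(l) list(
    layout_id = l$layout_id, mirrored = l$mirrored,
    obstacles = lapply(l$obstacles, function(ob)
      list(size_class = ob$size_class,
           x_center = (ob$xmin + ob$xmax) / 2,
           y_center = (ob$ymin + ob$ymax) / 2)))
  jsonlite::write_json(lapply(layouts, as_rec), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_layouts_json
#' @param corridor Corridor the layouts are validated against.
#' @export
read_layouts_json <- function(path, corridor = corridor_spec()) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    obs <- lapply(r$obstacles, function(ob)
      obstacle_spec(ob$size_class, ob$x_center, ob$y_center))
    route_layout(obs, layout_id = r$layout_id, mirrored = isTRUE(r$mirrored),
                 corridor = corridor, canonical = FALSE)
  })
}
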