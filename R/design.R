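# Trial-schedule construction: two sessions per participant, each starting
# with two camera-vision control trials (one per scene complexity) followed
# by 16 SPV trials (six CED resolutions and two surface-boundary resolutions,
# each at both complexities) in randomized order, with route layouts matched
# but mirrored across the two complexities of a condition and matched between
# the surface-boundary conditions and their CED counterparts.

.ced_resolutions <- c(10L, 18L, 26L, 34L, 42L, 50L)
.boundary_resolutions <- c(26L, 42L)

#' Study condition table
#'
#' The distinct study conditions: camera vision, CED-based SPV at six
#' phosphene resolutions, and surface-boundary SPV at two resolutions, each
#' crossed with scene complexity.
#'
#' @return Data frame with columns `vision`, `resolution`, `complexity`.
#' @export
condition_table <- function() {
  rbind(
    expand.grid(vision = "camera", resolution = NA_integer_,
                complexity = c("plain", "complex"),
                stringsAsFactors = FALSE),
    expand.grid(vision = "ced_spv", resolution = .ced_resolutions,
                complexity = c("plain", "complex"),
                stringsAsFactors = FALSE),
    expand.grid(vision = "boundary_spv", resolution = .boundary_resolutions,
                complexity = c("plain", "complex"),
                stringsAsFactors = FALSE))
}

#' Build a randomized per-participant trial schedule
#'
#' Generates the two-session schedule: per session, two camera control trials
#' first (complexity order randomized), then the 16 SPV condition instances
#' in a uniformly random order. Route-layout assignment satisfies the
#' matching constraints: the plain and complex trials of one condition share
#' a layout in mirrored orientations, and each surface-boundary condition
#' reuses the layout of its CED counterpart (same resolution, complexity and
#' session). The two sessions draw layouts independently. Deterministic
#' given `seed`.
#'
#' @param participant_id Identifier (kept as given).
#' @param seed Integer seed.
#' @param n_layouts Size of the base route-layout library (default 7; the
#'   mirrored versions are implied by the `mirrored` flag).
#' @return Data frame of class `spv_schedule` with columns `participant_id`,
#'   `session`, `index_in_session`, `vision`, `resolution`, `complexity`,
#'   `layout_id`, `mirrored`.
#' @export
build_trial_schedule <- function(participant_id, seed, n_layouts = 7L) {
  if (n_layouts < 1L) stop_contract("layout library too small (n_layouts < 1)")
  run_seeded(seed, build_schedule_unseeded(participant_id, n_layouts))
}

build_schedule_unseeded <- function(participant_id, n_layouts) {
  sessions <- lapply(1:2, function(s) {
    assign_pair <- function() {
      l <- sample.int(n_layouts, 1L)
      m <- sample(c(TRUE, FALSE), 1L)
      # plain gets (l, m), complex gets (l, !m)
      data.frame(complexity = c("plain", "complex"), layout_id = l,
                 mirrored = c(m, !m), stringsAsFactors = FALSE)
    }
    cam <- assign_pair()
    cam_rows <- data.frame(vision = "camera", resolution = NA_integer_,
                           cam, stringsAsFactors = FALSE)
    ced_rows <- do.call(rbind, lapply(.ced_resolutions, function(r) {
      p <- assign_pair()
      data.frame(vision = "ced_spv", resolution = r, p,
                 stringsAsFactors = FALSE)
    }))
    bnd_rows <- do.call(rbind, lapply(.boundary_resolutions, function(r) {
      p <- ced_rows[ced_rows$resolution == r, c("complexity", "layout_id",
                                                "mirrored")]
      data.frame(vision = "boundary_spv", resolution = r, p,
                 stringsAsFactors = FALSE)
    }))
    spv <- rbind(ced_rows, bnd_rows)
    spv <- spv[sample.int(nrow(spv)), ]
    cam <- cam_rows[sample.int(2L), ]
    out <- rbind(cam, spv)
    out$session <- s
    out$index_in_session <- seq_len(nrow(out))
    out
  })
  out <- do.call(rbind, sessions)
  out <- cbind(participant_id = participant_id,
               out[, c("session", "index_in_session", "vision", "resolution",
                       "complexity", "layout_id", "mirrored")])
  rownames(out) <- NULL
  class(out) <- c("spv_schedule", "data.frame")
  out
}

#' Build schedules for a whole experiment
#'
#' @param n_participants Number of participants (default 20).
#' @param seed Integer seed.
#' @param n_layouts Base layout library size.
#' @return Row-bound `spv_schedule` for participants `P01`, `P02`, ...
#' @export
build_experiment_schedule <- function(n_participants = 20L, seed = 1L,
                                      n_layouts = 7L) {
  out <- run_seeded(seed, do.call(rbind, lapply(seq_len(n_participants),
    function(i) build_schedule_unseeded(sprintf("P%02d", i), n_layouts))))
  class(out) <- c("spv_schedule", "data.frame")
  out
}

#' Verify a trial schedule against the design constraints
#'
#' Checks the per-participant trial counts (4 camera, 24 CED-SPV, 8
#' boundary-SPV over two sessions), session structure (18 contiguous slots,
#' camera controls first), the complexity mirror-matching constraint and the
#' method layout-matching constraint, reporting offending slots.
#'
#' @param schedule A schedule data frame as from [build_trial_schedule()].
#' @return Data frame of class `spv_schedule_check` with columns
#'   `constraint`, `pass`, `detail`; attribute `all_pass`.
#' @export
verify_schedule <- function(schedule) {
  if (!nrow(schedule)) stop_contract("empty schedule")
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      constraint = name, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (pid in unique(schedule$participant_id)) {
    ps <- schedule[schedule$participant_id == pid, ]
    counts <- table(factor(ps$vision,
                           levels = c("camera", "ced_spv", "boundary_spv")))
    want <- c(camera = 4L, ced_spv = 24L, boundary_spv = 8L)
    for (v in names(want)) {
      ok <- counts[[v]] == want[[v]]
      add(sprintf("count_%s", v), ok,
          if (ok) pid else sprintf("%s: %d trials of %s, expected %d",
                                   pid, counts[[v]], v, want[[v]]))
    }
    for (s in unique(ps$session)) {
      ss <- ps[ps$session == s, ]
      ss <- ss[order(ss$index_in_session), ]
      add("session_size", nrow(ss) == 18L,
          sprintf("%s session %d: %d slots", pid, s, nrow(ss)))
      add("indices_contiguous",
          identical(ss$index_in_session, seq_len(nrow(ss))),
          sprintf("%s session %d", pid, s))
      add("camera_first", all(ss$vision[seq_len(min(2L, nrow(ss)))] == "camera"),
          sprintf("%s session %d", pid, s))
      # Mirror matching across complexities of one condition.
      key_id <- paste(ss$vision, ss$resolution)
      for (k in unique(key_id)) {
        pair <- ss[key_id == k, ]
        if (nrow(pair) != 2L) {
          add("complexity_pair", FALSE,
              sprintf("%s session %d %s: %d trials", pid, s, k, nrow(pair)))
          next
        }
        ok <- length(unique(pair$layout_id)) == 1L &&
          sum(pair$mirrored) == 1L &&
          setequal(pair$complexity, c("plain", "complex"))
        add("complexity_pair_mirrored", ok,
            if (ok) "" else sprintf(
              "%s session %d %s: layouts %s mirrored %s", pid, s, k,
              paste(pair$layout_id, collapse = ","),
              paste(pair$mirrored, collapse = ",")))
      }
      # Method matching: boundary condition reuses its CED counterpart.
      bnd <- ss[ss$vision == "boundary_spv", ]
      for (k in seq_len(nrow(bnd))) {
        ced <- ss[ss$vision == "ced_spv" &
                    ss$resolution == bnd$resolution[k] &
                    ss$complexity == bnd$complexity[k], ]
        ok <- nrow(ced) == 1L && ced$layout_id == bnd$layout_id[k] &&
          ced$mirrored == bnd$mirrored[k]
        add("method_pair_matched", ok,
            if (ok) "" else sprintf(
              "%s session %d boundary %d/%s not matched to CED", pid, s,
              bnd$resolution[k], bnd$complexity[k]))
      }
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "all_pass") <- all(out$pass)
  class(out) <- c("spv_schedule_check", "data.frame")
  out
}

#' @export
print.spv_schedule_check <- function(x, ...) {
  agg <- aggregate(pass ~ constraint, data = as.data.frame(x), FUN = all)
  cat("<schedule check>", if (attr(x, "all_pass")) "all constraints pass"
      else "CONSTRAINT FAILURES", "\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-28s %s\n", agg$constraint[i],
                if (agg$pass[i]) "pass" else "FAIL"))
  fails <- x[!x$pass, ]
  if (nrow(fails))
    for (i in seq_len(nrow(fails)))
      cat("  ! ", fails$constraint[i], ": ", fails$detail[i], "\n", sep = "")
  invisible(x)
}

#' Write / read a schedule as CSV
#'
#' @param schedule A schedule data frame.
#' @param path CSV path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns the schedule.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("spv_schedule", "data.frame")
  out
}
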