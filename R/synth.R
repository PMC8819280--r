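# Synthetic behavioral data: a structural stand-in for the (unpublished)
# human trial records, with condition-level means, participant random
# effects matching the reported between-participant dispersions, a
# session-two learning shift, and bounded discrete endpoints, so the
# analysis pipeline can be exercised and calibrated without human data.

#' Default condition-level endpoint means
#'
#' A plausible default mean table anchored to the two published values
#' (camera-vision mean trial duration 16.74 s with zero collisions and a
#' rating near 9.4) and shaped qualitatively: SPV performance improves
#' monotonically with phosphene resolution, scene complexity penalizes the
#' low resolutions, the penalty vanishes and slightly reverses at 50 x 50,
#' and surface-boundary SPV trails its CED counterpart in the plain scene.
#' All values are configuration, not measurements.
#'
#' @param complexity_penalty_scale Multiplier on the complex-minus-plain
#'   offsets (1 = default effects; 0 = null generator with no complexity
#'   effect, used for type-I calibration).
#' @return Data frame with columns `vision`, `resolution`, `complexity`,
#'   `duration_s`, `collision_rate`, `rating`.
#' @export
default_condition_means <- function(complexity_penalty_scale = 1) {
  s <- complexity_penalty_scale
  res <- .ced_resolutions
  ced_dur <- c(44, 37, 31, 27, 25, 24)
  ced_dur_pen <- c(12, 8, 3, 1, 0, -2)
  ced_col <- c(1.5, 1.0, 0.7, 0.55, 0.45, 0.4)
  ced_col_pen <- c(1.0, 0.7, 0.4, 0.1, 0, -0.05)
  ced_rat <- c(3.5, 4.5, 5.5, 6.2, 6.7, 7.0)
  ced_rat_pen <- c(1.0, 0.9, 0.5, 0.2, 0, -0.2)
  bres <- .boundary_resolutions
  bnd_dur <- c(34, 28); bnd_dur_pen <- c(1, 2)
  bnd_col <- c(0.8, 0.55); bnd_col_pen <- c(0.3, 0.05)
  bnd_rat <- c(4.8, 5.8); bnd_rat_pen <- c(0.2, 0.3)
  out <- rbind(
    data.frame(vision = "camera", resolution = NA_integer_,
               complexity = c("plain", "complex"),
               duration_s = 16.74, collision_rate = 0, rating = 9.363,
               stringsAsFactors = FALSE),
    data.frame(vision = "ced_spv", resolution = rep(res, 2),
               complexity = rep(c("plain", "complex"), each = length(res)),
               duration_s = c(ced_dur, ced_dur + s * ced_dur_pen),
               collision_rate = pmax(0, c(ced_col, ced_col + s * ced_col_pen)),
               rating = clamp(c(ced_rat, ced_rat - s * ced_rat_pen), 1, 10),
               stringsAsFactors = FALSE),
    data.frame(vision = "boundary_spv", resolution = rep(bres, 2),
               complexity = rep(c("plain", "complex"), each = length(bres)),
               duration_s = c(bnd_dur, bnd_dur + s * bnd_dur_pen),
               collision_rate = pmax(0, c(bnd_col, bnd_col + s * bnd_col_pen)),
               rating = clamp(c(bnd_rat, bnd_rat - s * bnd_rat_pen), 1, 10),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Behavioral generator parameters
#'
#' @param condition_means Mean table as from [default_condition_means()].
#' @param participant_sd Named vector of between-participant SDs for the
#'   three endpoints; defaults are the reported dispersions (7.748 s trial
#'   duration, 0.251 collisions, 0.783 rating).
#' @param session2_duration_shift_s Additive duration shift applied to SPV
#'   trials of session 2 (default -3.468 s: a learning speed-up).
#' @param residual_sd Named vector of within-participant residual SDs for
#'   `duration_s` and `rating` (collisions carry Poisson noise).
#' @param min_duration_s Positive floor applied to sampled durations.
#' @param camera_zero_collisions Force camera-vision collisions to zero
#'   (the control condition is reported collision-free).
#' @return A `behavioral_model_params` list.
#' @export
behavioral_model_params <- function(
    condition_means = default_condition_means(),
    participant_sd = c(duration_s = 7.748, collisions = 0.251,
                       rating = 0.783),
    session2_duration_shift_s = -3.468,
    residual_sd = c(duration_s = 6, rating = 1.2),
    min_duration_s = 5,
    camera_zero_collisions = TRUE) {
  if (any(condition_means$duration_s <= 0))
    stop_contract("duration means must be positive")
  if (any(condition_means$collision_rate < 0))
    stop_contract("collision rates must be non-negative")
  if (any(condition_means$rating < 1 | condition_means$rating > 10))
    stop_contract("rating means must lie in [1, 10]")
  if (any(participant_sd < 0) || any(residual_sd < 0))
    stop_contract("dispersions must be non-negative")
  structure(list(condition_means = condition_means,
                 participant_sd = participant_sd,
                 session2_duration_shift_s = session2_duration_shift_s,
                 residual_sd = residual_sd,
                 min_duration_s = min_duration_s,
                 camera_zero_collisions = camera_zero_collisions),
            class = "behavioral_model_params")
}

#' Sample synthetic trial records for a schedule
#'
#' Endpoint model per trial:
#' \itemize{
#'   \item duration = condition mean + participant effect (normal, SD
#'     `participant_sd["duration_s"]`) + session-2 SPV shift + normal
#'     residual, floored at `min_duration_s`;
#'   \item collisions ~ Poisson(condition rate x participant frailty), with
#'     lognormal frailty of mean 1 scaled so the between-participant SD of
#'     mean collisions approximates `participant_sd["collisions"]`; camera
#'     trials forced to zero when configured;
#'   \item rating = condition mean + participant effect + residual, rounded
#'     and clipped to the 1-10 scale.
#' }
#'
#' @param schedule Schedule data frame (see [build_trial_schedule()]).
#' @param params A [behavioral_model_params()].
#' @param seed Integer seed.
#' @return The schedule with `duration_s`, `collisions`, `rating` columns
#'   appended; class `spv_trials`.
#' @export
sample_trials <- function(schedule, params = behavioral_model_params(),
                          seed = 1L) {
  stopifnot(inherits(params, "behavioral_model_params"))
  cm <- params$condition_means
  key <- function(d) paste(d$vision, d$resolution, d$complexity)
  idx <- match(key(schedule), key(cm))
  if (anyNA(idx))
    stop_contract("schedule contains conditions missing from the mean table: %s",
                  paste(unique(key(schedule)[is.na(idx)]), collapse = "; "))
  run_seeded(seed, {
    pid <- factor(schedule$participant_id)
    n_p <- nlevels(pid)
    u_dur <- rnorm(n_p, 0, params$participant_sd[["duration_s"]])[pid]
    u_rat <- rnorm(n_p, 0, params$participant_sd[["rating"]])[pid]
    spv_rates <- cm$collision_rate[cm$vision != "camera"]
    mean_rate <- mean(spv_rates)
    sd_target <- params$participant_sd[["collisions"]]
    sigma_log <- if (mean_rate > 0 && sd_target > 0)
      sqrt(log1p((sd_target / mean_rate)^2)) else 0
    frailty <- exp(rnorm(n_p, -sigma_log^2 / 2, sigma_log))[pid]

    mu_dur <- cm$duration_s[idx]
    is_spv <- schedule$vision != "camera"
    shift <- ifelse(is_spv & schedule$session == 2,
                    params$session2_duration_shift_s, 0)
    duration <- mu_dur + u_dur + shift +
      rnorm(nrow(schedule), 0, params$residual_sd[["duration_s"]])
    duration <- pmax(duration, params$min_duration_s)

    lambda <- cm$collision_rate[idx] * frailty
    collisions <- rpois(nrow(schedule), lambda)
    if (params$camera_zero_collisions)
      collisions[schedule$vision == "camera"] <- 0L

    rating <- cm$rating[idx] + u_rat +
      rnorm(nrow(schedule), 0, params$residual_sd[["rating"]])
    rating <- as.integer(clamp(round(rating), 1, 10))

    out <- cbind(as.data.frame(schedule), duration_s = duration,
                 collisions = collisions, rating = rating)
    class(out) <- c("spv_trials", "data.frame")
    out
  })
}

#' Write / read trial records as CSV
#'
#' @param trials Trial-record data frame.
#' @param path CSV path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns the records.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("spv_trials", "data.frame")
  out
}
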