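# Nonparametric analysis pipeline: within-participant standardization, exact
# and approximate Wilcoxon signed-rank tests, Bonferroni-adjusted planned
# comparisons over the complexity and image-processing families, normality
# screening, the learning-effect summary and the restoration-percentage
# metric.

.endpoints <- c("duration_s", "collisions", "rating")

#' Standardize endpoints within participants
#'
#' Z-scores each endpoint over all of a participant's trials (control trials
#' included): the participant's mean is subtracted and the result divided by
#' the participant's standard deviation, removing inter-individual
#' differences in walking speed, avoidance strategy and rating use.
#'
#' @param records Trial records (see [sample_trials()]).
#' @param endpoints Endpoint columns to standardize.
#' @return The records with `<endpoint>_z` columns appended; class
#'   `spv_trials_z`.
#' @export
standardize_within_participant <- function(records, endpoints = .endpoints) {
  for (e in endpoints)
    if (!e %in% names(records))
      stop_contract("records lack endpoint column '%s'", e)
  out <- as.data.frame(records)
  pid <- factor(records$participant_id)
  for (e in endpoints) {
    mu <- ave(out[[e]], pid, FUN = mean)
    sdv <- ave(out[[e]], pid, FUN = sd)
    bad <- !is.na(sdv) & sdv == 0
    if (any(bad)) {
      who <- unique(out$participant_id[bad])
      stop_contract("degenerate data: zero spread in endpoint '%s' for participant(s) %s",
                    e, paste(who, collapse = ", "))
    }
    out[[paste0(e, "_z")]] <- (out[[e]] - mu) / sdv
  }
  class(out) <- c("spv_trials_z", "data.frame")
  out
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with Wilcoxon's zero-handling (zero differences
#' dropped) and mid-ranks for tied absolute differences. For up to
#' `exact_max_n` informative pairs the two-sided p-value comes from exact
#' enumeration of all sign patterns of the observed absolute ranks (valid
#' under ties); beyond that, a normal approximation with tie correction and
#' continuity correction is used. The statistic `W` is the positive-rank sum.
#'
#' @param x Numeric vector of differences, or first member of pairs.
#' @param y Optional second member; differences are `x - y`.
#' @param exact_max_n Largest informative n for the exact path (default 15).
#' @return List with `W`, `p`, `n_informative`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 15L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop_contract("no information: all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # Null distribution of W+ over all 2^n equiprobable sign patterns,
    # by convolution over the observed ranks (valid under mid-ranked ties;
    # ranks may be half-integers, so work on doubled ranks).
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)
    dist[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), dist[seq_len(length(dist) - rr)])
      dist <- (dist + shifted) / 2
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, p = p, n_informative = n, method = method)
}

#' Per-participant condition means of standardized endpoints
#'
#' The pairing unit for the planned comparisons: the mean of a participant's
#' (typically two) trials of one condition, per endpoint, after
#' standardization.
#'
#' @param z Standardized records from [standardize_within_participant()].
#' @return Data frame keyed by `participant_id`, `vision`, `resolution`,
#'   `complexity` with `<endpoint>_z` means.
#' @export
condition_means_by_participant <- function(z) {
  zcols <- grep("_z$", names(z), value = TRUE)
  agg <- aggregate(z[zcols],
                   by = list(participant_id = z$participant_id,
                             vision = z$vision,
                             resolution = ifelse(is.na(z$resolution), -1L,
                                                 z$resolution),
                             complexity = z$complexity),
                   FUN = mean)
  agg$resolution[agg$resolution == -1L] <- NA_integer_
  agg
}

#' Run the planned paired comparisons with Bonferroni control
#'
#' Two comparison families per endpoint:
#' \itemize{
#'   \item scene complexity: plain vs complex CED-SPV at each of the six
#'     phosphene resolutions (family size 6, per-test threshold
#'     `alpha / 6`, displayed as 0.0083 at `alpha = 0.05`);
#'   \item image processing: surface-boundary SPV vs CED-SPV at each
#'     measured resolution-complexity subcondition (family size 4,
#'     displayed threshold 0.0125).
#' }
#' Each comparison is a Wilcoxon signed-rank test on the per-participant
#' condition means of the standardized endpoint. A comparison with all-zero
#' differences is reported with `p = NA` and a note instead of failing.
#'
#' @param records Trial records; standardized internally if no `_z` columns
#'   are present.
#' @param alpha Family-wise significance level (default 0.05).
#' @param endpoints Endpoints to test.
#' @return Data frame of class `spv_stats_report`: one row per comparison
#'   with `family`, `endpoint`, `resolution`, `complexity`, `n_pairs`, `W`,
#'   `p`, `m`, `adj_alpha`, `adj_alpha_displayed`, `significant`, `note`.
#' @export
run_planned_comparisons <- function(records, alpha = 0.05,
                                    endpoints = .endpoints) {
  z <- if (any(grepl("_z$", names(records)))) records
  else standardize_within_participant(records, endpoints)
  cm <- condition_means_by_participant(z)
  rows <- list()
  test_pair <- function(a, b, family, endpoint, resolution, complexity, m) {
    key <- paste(a$participant_id)
    b <- b[match(a$participant_id, b$participant_id), ]
    if (anyNA(b$participant_id))
      stop_contract("pairing error: participants missing condition (%s, %s)",
                    family, endpoint)
    col <- paste0(endpoint, "_z")
    res <- tryCatch(wilcoxon_signed_rank(a[[col]], b[[col]]),
                    error = function(e) NULL)
    data.frame(family = family, endpoint = endpoint,
               resolution = resolution,
               complexity = if (is.null(complexity)) NA_character_ else complexity,
               n_pairs = nrow(a),
               W = if (is.null(res)) NA_real_ else res$W,
               p = if (is.null(res)) NA_real_ else res$p,
               m = m, adj_alpha = alpha / m,
               adj_alpha_displayed = round(alpha / m, 4),
               significant = if (is.null(res)) FALSE else res$p < alpha / m,
               note = if (is.null(res)) "no information (all differences zero)"
               else "", stringsAsFactors = FALSE)
  }
  for (e in endpoints) {
    for (r in .ced_resolutions) {
      a <- cm[cm$vision == "ced_spv" & cm$resolution == r &
                cm$complexity == "complex", ]
      b <- cm[cm$vision == "ced_spv" & cm$resolution == r &
                cm$complexity == "plain", ]
      rows[[length(rows) + 1L]] <-
        test_pair(a, b, "complexity", e, r, NULL, m = 6L)
    }
    for (r in .boundary_resolutions) for (cx in c("plain", "complex")) {
      a <- cm[cm$vision == "boundary_spv" & cm$resolution == r &
                cm$complexity == cx, ]
      b <- cm[cm$vision == "ced_spv" & cm$resolution == r &
                cm$complexity == cx, ]
      rows[[length(rows) + 1L]] <-
        test_pair(a, b, "method", e, r, cx, m = 4L)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spv_stats_report", "data.frame")
  out
}

#' @export
print.spv_stats_report <- function(x, ...) {
  cat("<planned comparisons> Wilcoxon signed-rank, Bonferroni-adjusted\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  print.data.frame(df[, c("family", "endpoint", "resolution", "complexity",
                          "n_pairs", "W", "p", "adj_alpha_displayed",
                          "significant")], row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory normality check of each standardized endpoint's per-participant
#' condition-mean distribution; the pipeline proceeds with rank tests
#' regardless of the outcome.
#'
#' @param z Standardized records.
#' @param endpoints Endpoints to screen.
#' @return Data frame with `endpoint`, `W`, `p`, `n`.
#' @export
shapiro_wilk_screen <- function(z, endpoints = .endpoints) {
  out <- lapply(endpoints, function(e) {
    v <- z[[paste0(e, "_z")]]
    v <- v[!is.na(v)]
    if (length(v) < 3L)
      stop_contract("Shapiro-Wilk requires n >= 3 (endpoint '%s')", e)
    if (length(unique(v)) == 1L)
      stop_contract("constant sample in endpoint '%s'", e)
    if (length(v) > 5000L) v <- v[seq_len(5000L)]
    s <- shapiro.test(v)
    data.frame(endpoint = e, W = unname(s$statistic), p = s$p.value,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Learning-effect summary
#'
#' Pearson correlation between the overall trial number and the standardized
#' trial duration, pooled across participants, plus the session shift: the
#' mean session-2 minus session-1 SPV trial duration in seconds (negative
#' when the second session is faster).
#'
#' @param records Trial records (raw durations required).
#' @return List with `pearson_r`, `p`, `session_shift_s`.
#' @export
learning_effect <- function(records) {
  if (nrow(records) < 3L) stop_contract("need at least 3 trials")
  ord <- order(records$participant_id, records$session,
               records$index_in_session)
  rec <- records[ord, ]
  trial_no <- ave(seq_len(nrow(rec)), rec$participant_id, FUN = seq_along)
  z <- standardize_within_participant(rec, "duration_s")
  if (sd(trial_no) == 0 || sd(z$duration_s_z) == 0)
    stop_contract("zero variance in trial number or duration")
  ct <- stats::cor.test(trial_no, z$duration_s_z, method = "pearson")
  spv <- rec[rec$vision != "camera", ]
  shift <- mean(spv$duration_s[spv$session == 2]) -
    mean(spv$duration_s[spv$session == 1])
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       session_shift_s = shift)
}

#' Restoration percentage
#'
#' Expresses a condition's performance on a 0-100 scale anchored at a floor
#' (worst SPV condition) and a ceiling (normal camera vision):
#' `100 * (floor - x) / (floor - ceiling)` when lower values are better,
#' `100 * (x - floor) / (ceiling - floor)` when higher values are better.
#' Values outside `[0, 100]` are reported as-is.
#'
#' @param x Observed value(s).
#' @param floor_value Performance floor (0% anchor).
#' @param ceiling_value Performance ceiling (100% anchor).
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @return Percentage(s).
#' @export
restoration_percentage <- function(x, floor_value, ceiling_value,
                                   direction = c("lower_is_better",
                                                 "higher_is_better")) {
  direction <- match.arg(direction)
  if (floor_value == ceiling_value)
    stop_contract("floor and ceiling must differ")
  if (direction == "lower_is_better")
    100 * (floor_value - x) / (floor_value - ceiling_value)
  else
    100 * (x - floor_value) / (ceiling_value - floor_value)
}

#' Speed-accuracy trade-off screen
#'
#' Plain least-squares slope of collisions on trial duration within each SPV
#' condition, with a sign summary: a consistently negative slope would
#' indicate participants trading speed against collisions.
#'
#' @param records Trial records.
#' @return Data frame with one row per condition (`vision`, `resolution`,
#'   `complexity`, `slope`, `p`), plus attribute `mean_slope`.
#' @export
speed_accuracy_slope <- function(records) {
  spv <- records[records$vision != "camera", ]
  key <- interaction(spv$vision, spv$resolution, spv$complexity, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- spv[key == k, ]
    if (nrow(d) < 3L || sd(d$duration_s) == 0)
      return(NULL)
    fit <- summary(lm(collisions ~ duration_s, data = d))
    data.frame(condition = k, slope = fit$coefficients[2, 1],
               p = fit$coefficients[2, 4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_slope") <- mean(out$slope)
  out
}
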