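# Standardization, Wilcoxon signed-rank, planned comparisons, screening,
# learning effect and restoration percentage.

make_records <- function(n_participants = 8, seed = 1,
                         params = behavioral_model_params()) {
  sch <- build_experiment_schedule(n_participants, seed = seed)
  sample_trials(sch, params, seed = seed + 100)
}

test_that("standardization yields per-participant mean 0 and SD 1", {
  tr <- make_records(6, seed = 2)
  z <- standardize_within_participant(tr)
  for (e in c("duration_s", "collisions", "rating")) {
    mu <- tapply(z[[paste0(e, "_z")]], z$participant_id, mean)
    sdv <- tapply(z[[paste0(e, "_z")]], z$participant_id, sd)
    expect_lt(max(abs(mu)), 1e-9)
    expect_lt(max(abs(sdv - 1)), 1e-9)
  }
})

test_that("zero spread raises a degenerate-data error naming the culprit", {
  tr <- make_records(3, seed = 3)
  tr$rating[tr$participant_id == "P02"] <- 5L
  expect_error(standardize_within_participant(tr), "rating.*P02")
})

test_that("standardization is invariant to positive affine transforms", {
  tr <- make_records(4, seed = 4)
  z1 <- standardize_within_participant(tr)
  tr2 <- tr
  tr2$duration_s <- 3.7 * tr2$duration_s + 11
  z2 <- standardize_within_participant(tr2)
  expect_equal(z1$duration_s_z, z2$duration_s_z, tolerance = 1e-12)
})

test_that("exact Wilcoxon matches enumeration and known values", {
  # n = 5, all differences positive: two-sided p = 2/32
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(res$p, 0.0625)
  expect_equal(res$W, 15)
  # brute-force enumeration on random data with ties and zeros
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    d <- sample(c(-3:3), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    mine <- wilcoxon_signed_rank(d)
    want <- bf_wilcoxon(d)
    expect_equal(mine$W, want$W)
    expect_equal(mine$p, want$p, tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(5)
  for (rep in 1:10) {
    d <- round(rnorm(12), 6)
    mine <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$W, unname(ref$statistic))
  }
  d <- rnorm(40)
  mine <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$method, "normal approximation")
})

test_that("swapping the pair order reflects W and preserves p", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  n <- a$n_informative
  expect_equal(a$W + b$W, n * (n + 1) / 2)
})

test_that("all-zero differences raise a no-information error", {
  expect_error(wilcoxon_signed_rank(rep(0, 8)), "no information")
})

test_that("planned comparisons report the Bonferroni-adjusted thresholds", {
  tr <- make_records(8, seed = 7)
  rep <- run_planned_comparisons(tr, alpha = 0.05)
  cx <- rep[rep$family == "complexity", ]
  me <- rep[rep$family == "method", ]
  expect_equal(nrow(cx), 6L * 3L)
  expect_equal(nrow(me), 4L * 3L)
  expect_true(all(cx$adj_alpha_displayed == 0.0083))
  expect_true(all(me$adj_alpha_displayed == 0.0125))
  expect_true(all(cx$adj_alpha == 0.05 / 6))
  expect_true(all(me$adj_alpha == 0.05 / 4))
  ok <- !is.na(rep$p)
  expect_equal(unname(rep$significant[ok]), unname(rep$p < rep$adj_alpha)[ok])
  # growing the family never makes a fixed p significant
  expect_true(all(!(rep$p[ok] >= rep$adj_alpha[ok] & rep$significant[ok])))
})

test_that("identical paired conditions surface a no-information note", {
  # boundary means identical to CED means + zero noise -> all method-family
  # differences are exactly zero
  cm <- default_condition_means()
  for (r in c(26L, 42L)) for (cx in c("plain", "complex")) {
    src <- cm$vision == "ced_spv" & cm$resolution == r & cm$complexity == cx
    dst <- cm$vision == "boundary_spv" & cm$resolution == r &
      cm$complexity == cx
    cm[dst, c("duration_s", "collision_rate", "rating")] <-
      cm[src, c("duration_s", "collision_rate", "rating")]
  }
  params <- behavioral_model_params(
    condition_means = cm,
    participant_sd = c(duration_s = 0, collisions = 0, rating = 0),
    session2_duration_shift_s = 0,
    residual_sd = c(duration_s = 0, rating = 0))
  sch <- build_experiment_schedule(6, seed = 11)
  tr <- sample_trials(sch, params, seed = 2)
  tr$collisions <- 0L  # drop Poisson noise: fully deterministic records
  rep <- run_planned_comparisons(tr, endpoints = "duration_s")
  me <- rep[rep$family == "method", ]
  expect_true(all(is.na(me$p)))
  expect_true(all(grepl("no information", me$note)))
  expect_true(all(!me$significant))
})

test_that("the normality screen is calibrated and detects skew", {
  set.seed(31)
  fake_z <- function(v) {
    data.frame(participant_id = "P", duration_s_z = v, collisions_z = v,
               rating_z = v)
  }
  rej <- mean(vapply(1:200, function(k) {
    shapiro_wilk_screen(fake_z(rnorm(50)), endpoints = "duration_s")$p < 0.05
  }, logical(1)))
  expect_lt(rej, 0.10)
  rej_skew <- mean(vapply(1:100, function(k) {
    shapiro_wilk_screen(fake_z(exp(rnorm(50))), endpoints = "duration_s")$p < 0.05
  }, logical(1)))
  expect_gt(rej_skew, 0.5)
  expect_error(shapiro_wilk_screen(fake_z(rep(1, 10))), "constant")
  expect_error(shapiro_wilk_screen(fake_z(c(1, 2))), "n >= 3")
})

test_that("learning effect: sign, permutation null, exact shift recovery", {
  # strictly decreasing durations -> negative correlation
  sch <- build_trial_schedule("P01", seed = 13)
  tr <- as.data.frame(sch)
  ord <- order(tr$session, tr$index_in_session)
  tr$duration_s <- 0
  tr$duration_s[ord] <- seq(60, 25, length.out = 36)
  tr$collisions <- 0L; tr$rating <- 5L
  le <- learning_effect(tr)
  expect_lt(le$pearson_r, -0.9)
  # permutation destroys the correlation
  set.seed(8)
  big <- make_records(20, seed = 21)
  rs <- vapply(1:100, function(k) {
    sh <- big
    sh$duration_s <- sample(sh$duration_s)
    abs(learning_effect(sh)$pearson_r)
  }, numeric(1))
  expect_lt(mean(rs), 0.05)
  # zero residual: the session shift parameter is recovered exactly
  params <- behavioral_model_params(
    participant_sd = c(duration_s = 2, collisions = 0, rating = 0),
    session2_duration_shift_s = -3.468,
    residual_sd = c(duration_s = 0, rating = 0))
  tr2 <- sample_trials(build_experiment_schedule(5, seed = 3), params,
                       seed = 4)
  expect_equal(learning_effect(tr2)$session_shift_s, -3.468,
               tolerance = 1e-9)
})

test_that("restoration percentage anchors and linearity", {
  expect_equal(restoration_percentage(10, floor_value = 50,
                                      ceiling_value = 10), 100)
  expect_equal(restoration_percentage(50, 50, 10), 0)
  expect_equal(restoration_percentage(30, 50, 10), 50)
  expect_equal(restoration_percentage(5, 0, 10, "higher_is_better"), 50)
  expect_equal(restoration_percentage(60, 50, 10), -25)  # unclamped
  expect_error(restoration_percentage(1, 5, 5), "differ")
})

test_that("speed-accuracy screen returns per-condition slopes", {
  tr <- make_records(10, seed = 17)
  sl <- speed_accuracy_slope(tr)
  expect_true(all(is.finite(sl$slope)))
  expect_equal(nrow(sl), 16L)  # 12 CED + 4 boundary conditions
  expect_true(is.finite(attr(sl, "mean_slope")))
})
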