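#' @importFrom stats rnorm runif rpois sd cor complete.cases pnorm shapiro.test
#'   aggregate lm coef median quantile
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
run_seeded <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_contract("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_contract("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_contract("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_contract("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Shift a matrix by (di, dj) with reflective (mirror) border handling.
shift_reflect <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- reflect_index(seq_len(nr) + di, nr)
  ci <- reflect_index(seq_len(nc) + dj, nc)
  m[ri, ci, drop = FALSE]
}

# Reflect out-of-range 1-based indices back into [1, n] with the edge pixel
# duplicated (0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1).
reflect_index <- function(idx, n) {
  j <- (idx - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
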