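# Internal helpers shared across the pipeline.

# Deterministic child seed derived from a master seed and a character scope.
# Keeps every derived seed inside the 32-bit signed range so it can be passed
# to set.seed() on any platform.
derive_seed <- function(master, ...) {
  scope <- paste(c(...), collapse = "/")
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(scope)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# round() uses banker's rounding; train/test boundaries use half-away-from-zero
# so 108 cases at 0.8 give 86 train / 22 test.
round_half_up <- function(x) floor(x + 0.5)

stop_lungchaos <- function(message, class, ...) {
  abort(message, class = c(class, "lungchaos_error"), ...)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_lungchaos(
      sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
      "lungchaos_config_error"
    )
  }
  invisible(x)
}

assert_quantiles <- function(q, name) {
  if (length(q) != 5L || any(!is.finite(q)) || is.unsorted(q)) {
    stop_lungchaos(
      sprintf("`%s` must be 5 nondecreasing finite values (min, Q1, median, Q3, max)", name),
      "lungchaos_config_error"
    )
  }
  invisible(q)
}

# Piecewise-linear quantile function through (min, Q1, median, Q3, max);
# inverse-CDF sampling for variables the study reports only as summaries.
sample_from_quantiles <- function(n, q) {
  p <- c(0, 0.25, 0.5, 0.75, 1)
  u <- runif(n)
  approx(p, q, xout = u, ties = "ordered")$y
}
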