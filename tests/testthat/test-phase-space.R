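# Embedding, portraits, delay selection and close returns.

test_that("delay embedding enumerates exactly the expected tuples", {
  expect_equal(delay_embed(c(1, 2, 3, 4), embedding_config(1, 2)),
               cbind(c(1, 2, 3), c(2, 3, 4)))
  x <- rnorm(50)
  expect_equal(delay_embed(x, embedding_config(3, 1)), matrix(x, ncol = 1))
  expect_equal(delay_embed(c(1, 2, 3, 4, 5, 6), embedding_config(2, 3)),
               cbind(c(1, 2), c(3, 4), c(5, 6)))
  # count formula across a parameter sweep
  for (tau in c(1, 2, 5)) {
    for (m in c(1, 2, 4)) {
      expect_equal(nrow(delay_embed(seq_len(60), embedding_config(tau, m))),
                   60 - (m - 1) * tau)
    }
  }
  expect_error(delay_embed(1:4, embedding_config(2, 3)),
               class = "lungchaos_length_error")
})

test_that("derivative portrait of a sinusoid traces a closed ellipse", {
  rate <- 4410; f <- 49  # period exactly 90 samples
  period <- rate / f
  x <- sine_samples(f, rate, 20 / f)
  pts <- derivative_portrait(x, smoothing = 5)
  omega <- 2 * pi * f / rate  # slope amplitude per sample
  radial <- pts[, 1]^2 + (pts[, 2] / omega)^2
  expect_lt(max(abs(radial - 1)), 0.05)
  # closure: each point returns to itself one period later, to well under 1%
  # of the orbit circumference (~2 pi in normalized coordinates)
  q <- cbind(pts[, 1], pts[, 2] / omega)
  n <- nrow(q)
  gaps <- sqrt(rowSums((q[1:(n - period), ] - q[(period + 1):n, ])^2))
  expect_lt(max(gaps), 2 * pi / 100)
})

test_that("derivative portrait degenerate cases behave as documented", {
  pts <- derivative_portrait(rep(0.3, 500), smoothing = 5)
  expect_true(all(abs(pts[, 1] - 0.3) < 1e-12))
  expect_true(all(abs(pts[, 2]) < 1e-12))
  ramp <- derivative_portrait(0.001 * (1:500), smoothing = 1)
  expect_true(all(abs(ramp[, 2] - 0.001) < 1e-12))
  expect_error(derivative_portrait(1:5, smoothing = 5),
               class = "lungchaos_length_error")
})

# Independent MI oracle using table()-based joint frequencies.
mi_oracle <- function(x, lag, bins = 16L) {
  n <- length(x) - lag
  cut_all <- cut(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                 include.lowest = TRUE)
  j <- table(cut_all[1:n], cut_all[(lag + 1):(lag + n)]) / n
  px <- rowSums(j); py <- colSums(j)
  keep <- j > 0
  sum(j[keep] * log(j[keep] / outer(px, py)[keep]))
}

test_that("delay selection lands on the quarter-period scale of a sinusoid", {
  rate <- 1000; f <- 10
  x <- sine_samples(f, rate, 4)
  d <- select_delay(x, max_lag = 40)
  # the binned-AMI basin of a sinusoid is broad; any delay on the
  # quarter-period scale gives an equivalent embedding
  expect_gte(d, rate / (8 * f))
  expect_lte(d, rate / (2 * f))
  # oracle: an independent table()-based MI curve, same smoothing and
  # qualification rule, picks the same minimum
  mi <- vapply(1:40, function(l) mi_oracle(x, l), numeric(1))
  sm <- as.numeric(stats::filter(mi, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(mi[1:2]); sm[40] <- mean(mi[39:40])
  cand <- which(vapply(2:39, function(k) {
    sm[k] <= sm[k - 1] && sm[k] <= sm[k + 1] && sm[k] <= 0.8 * sm[1]
  }, logical(1))) + 1L
  expect_lt(abs(d - cand[1]), 3)
})

test_that("delay selection falls back to lag 1 on white noise and rejects constants", {
  x <- withr::with_seed(10, rnorm(5000))
  expect_equal(select_delay(x, max_lag = 30), 1L)
  expect_error(select_delay(rep(1, 1000)), class = "lungchaos_degenerate_error")
})

test_that("portrait library enumeration is deterministic, pegged at 300", {
  lib <- build_library()
  expect_equal(nrow(lib), 300L)
  expect_equal(lib$portrait_id, 0:299)
  expect_identical(lib, build_library())
  small <- build_library(portrait_library_config(
    bands = list(NULL, c(50, 500)),
    delays = c(1L, 2L, 4L),
    transforms = "delay_pair",
    target_size = 6L
  ))
  expect_equal(nrow(small), 6L)
  expect_error(
    build_library(portrait_library_config(
      bands = list(NULL), delays = c(1L, 2L), transforms = "delay_pair",
      target_size = 10L
    )),
    class = "lungchaos_library_too_small_error"
  )
})

test_that("portrait transforms produce the documented point sets", {
  x <- chaotic_samples(duration = 2)[1:2000]
  spec_dp <- list(portrait_id = 0L, band_low = NA_real_, band_high = NA_real_,
                  transform = "delay_pair", delay = 3L, smoothing = NA_integer_)
  p <- apply_portrait(x, spec_dp, 4410)
  expect_equal(p$points[, 1], x[1:(2000 - 3)], ignore_attr = TRUE)
  expect_equal(p$points[, 2], x[4:2000], ignore_attr = TRUE)

  spec_dv <- modifyList(spec_dp, list(transform = "derivative", smoothing = 5L))
  p2 <- apply_portrait(x, spec_dv, 4410)
  expect_equal(p2$points, derivative_portrait(x, 5))

  bad <- modifyList(spec_dp, list(band_low = 100, band_high = 3000))
  expect_error(apply_portrait(x, bad, 4410), class = "lungchaos_spec_error")
})

test_that("band-passed noise delay pairs show the band autocorrelation at the lag", {
  x <- withr::with_seed(11, rnorm(20000))
  spec <- list(portrait_id = 0L, band_low = 200, band_high = 600,
               transform = "delay_pair", delay = 2L, smoothing = NA_integer_)
  p <- apply_portrait(x, spec, 4410)
  filtered <- lungchaos:::portrait_filter(x, 200, 600, 4410)
  r_direct <- acf(filtered, lag.max = 2, plot = FALSE)$acf[3]
  expect_equal(cor(p$points[, 1], p$points[, 2]), r_direct, tolerance = 0.02)
})

test_that("close returns concentrate at the period of a periodic orbit", {
  x <- sine_samples(10, 1000, 1)  # period 100 samples
  emb <- delay_embed(x, embedding_config(25, 2))
  cr <- close_returns(emb, eps = 0.05, min_period = 50, max_period = 250)
  expect_gt(nrow(cr), 0)
  off <- abs(((cr$period + 50) %% 100) - 50)  # distance to nearest multiple of 100
  expect_true(all(off <= 2))
  expect_false(is.unsorted(cr$return_distance))
})

test_that("close returns handle degenerate radii as documented", {
  pts <- matrix(withr::with_seed(12, rnorm(200)), ncol = 2)
  # iid noise at tiny eps: empty or nearly so
  tiny <- close_returns(pts, eps = 1e-4, min_period = 5, max_period = 50)
  expect_lte(nrow(tiny), 2)
  # infinite radius: every admissible (i, p) pair
  all_pairs <- close_returns(pts, eps = Inf, min_period = 5, max_period = 50)
  n <- nrow(pts)
  expected <- sum(vapply(1:n, function(i) max(0, min(50, n - i) - 5 + 1), numeric(1)))
  expect_equal(nrow(all_pairs), expected)
  expect_error(close_returns(matrix(numeric(0), ncol = 2), 1, 1, 2),
               class = "lungchaos_input_error")
})
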