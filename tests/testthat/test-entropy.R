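# Occupancy entropies, column entropies, and the entropic collapse.

cluster_points <- function(centers, counts, spread = 0) {
  do.call(rbind, purrr::map2(centers, counts, function(ctr, n) {
    cbind(rep(ctr[1], n), rep(ctr[2], n)) +
      if (spread > 0) matrix(rnorm(2 * n, 0, spread), ncol = 2) else 0
  }))
}

test_that("occupancy entropy evaluates exactly on engineered histograms", {
  b <- binning_config(nx = 4, ny = 4)
  # evenly split over 4 distinct cells -> 2 bits
  pts4 <- cluster_points(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                         c(50, 50, 50, 50))
  expect_equal(as.numeric(occupancy_entropy(pts4, b)), 2)
  # everything in one cell -> 0 bits, flagged degenerate
  one <- occupancy_entropy(cluster_points(list(c(0.5, 0.5)), 200), b)
  expect_equal(as.numeric(one), 0)
  expect_true(attr(one, "degenerate"))
  # proportions (1/2, 1/4, 1/4) -> 1.5 bits
  pts3 <- cluster_points(list(c(0, 0), c(0, 1), c(1, 0)), c(100, 50, 50))
  expect_equal(as.numeric(occupancy_entropy(pts3, b)), 1.5)
  expect_error(occupancy_entropy(pts3[1:50, ], b), class = "lungchaos_length_error")
})

test_that("occupancy entropy respects its bounds on arbitrary portraits", {
  b <- binning_config()
  for (seed in 1:5) {
    pts <- matrix(withr::with_seed(seed, rnorm(400)), ncol = 2)
    h <- as.numeric(occupancy_entropy(pts, b))
    expect_gte(h, 0)
    expect_lte(h, log2(b$nx * b$ny))
  }
})

test_that("column entropy separates clustered from diffuse features", {
  b <- binning_config()
  expect_identical(column_entropy(rep(3.3, 20), b), Inf)
  bimodal <- c(rnorm(50, -1, 0.01), rnorm(50, 1, 0.01))
  h_bi <- column_entropy(bimodal, b)
  expect_equal(h_bi, 1, tolerance = 0.05)
  h_norm <- column_entropy(withr::with_seed(30, rnorm(10000)), b)
  expect_gt(h_norm, h_bi)
  expect_lte(h_norm, log2(b$column_bins))
  expect_error(column_entropy(1:5, b), class = "lungchaos_insufficient_data_error")
})

test_that("featurize yields one ordered entropy per portrait, deterministically", {
  lib <- build_library(portrait_library_config(
    bands = list(NULL, c(60, 600)),
    delays = c(1L, 2L, 4L, 8L),
    smoothings = c(5L),
    target_size = 10L
  ))
  rec <- withr::with_seed(31, generate_recording(
    list(subject_id = "S1", group = "COPD"), "egophony",
    acoustic_config(duration = 2)))
  v1 <- featurize(rec, lib)
  v2 <- featurize(rec, lib)
  expect_length(v1, nrow(lib))
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
})

test_that("a sinusoid scores lower delay-pair entropy than a chaotic signal", {
  b <- binning_config()
  spec <- list(portrait_id = 0L, band_low = NA_real_, band_high = NA_real_,
               transform = "delay_pair", delay = 8L, smoothing = NA_integer_)
  chaotic <- chaotic_samples(duration = 5)[1:8000]
  sine <- 0.9 * sine_samples(135, 4410, 8000 / 4410)[1:8000]
  h_sine <- occupancy_entropy(apply_portrait(sine, spec, 4410), b)
  h_chaos <- occupancy_entropy(apply_portrait(chaotic, spec, 4410), b)
  expect_lt(as.numeric(h_sine), as.numeric(h_chaos))
})

make_features <- function(n = 30, k = 20, bimodal_at = c(4, 11), seed = 32) {
  vals <- withr::with_seed(seed, {
    m <- matrix(rnorm(n * k), nrow = n)
    for (j in bimodal_at) {
      m[, j] <- c(rnorm(n %/% 2, -2, 0.02), rnorm(n - n %/% 2, 2, 0.02))
    }
    m
  })
  colnames(vals) <- sprintf("p%03d", seq_len(k) - 1L)
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), site = "egophony"),
    tibble::as_tibble(vals)
  )
}

test_that("collapse selects the engineered bimodal pair and matches brute force", {
  feats <- make_features()
  res <- collapse(feats)
  expect_setequal(res$selected_portraits, c("p003", "p010"))
  expect_equal(res$search_method, "exhaustive")
  # brute-force oracle over all 190 pairs
  cols <- sprintf("p%03d", 0:19)
  ents <- vapply(cols, function(cn) column_entropy(feats[[cn]]), numeric(1))
  pairs <- utils::combn(20, 2)
  objs <- ents[pairs[1, ]] + ents[pairs[2, ]]
  best <- pairs[, which.min(objs)]
  expect_setequal(res$selected_portraits, cols[best])
  expect_equal(res$objective, min(objs), tolerance = 1e-12)
  # coordinates are the selected columns, row-aligned
  expect_equal(res$coordinates$d1, feats$p003)
  expect_equal(res$coordinates$d2, feats$p010)
})

test_that("exact entropy ties break toward the lowest portrait-id pair", {
  feats <- make_features(bimodal_at = integer(0))
  # three identical bimodal columns: p005, p002, p009 (all same values)
  bim <- c(rep(-2, 15), rep(2, 15))
  feats$p005 <- bim; feats$p002 <- bim; feats$p009 <- bim
  res <- collapse(feats)
  expect_identical(res$selected_portraits, c("p002", "p005"))
})

test_that("collapse never consults labels and is invariant to row order", {
  feats <- make_features(seed = 33)
  res1 <- collapse(feats)
  shuffled <- withr::with_seed(34, feats[sample(nrow(feats)), ])
  res2 <- collapse(shuffled)
  expect_identical(res1$selected_portraits, res2$selected_portraits)
  expect_identical(res1$objective, res2$objective)
  reordered <- res2$coordinates[match(res1$coordinates$subject_id,
                                      res2$coordinates$subject_id), ]
  expect_identical(res1$coordinates$d1, reordered$d1)
})

test_that("greedy search on wide matrices agrees with the additive optimum", {
  n <- 12; k <- 410
  vals <- withr::with_seed(35, matrix(rnorm(n * k), nrow = n))
  colnames(vals) <- sprintf("p%03d", seq_len(k) - 1L)
  feats <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), site = "x"),
    tibble::as_tibble(vals)
  )
  res <- collapse(feats)
  expect_equal(res$search_method, "greedy")
  ents <- vapply(sprintf("p%03d", 0:(k - 1)),
                 function(cn) column_entropy(feats[[cn]]), numeric(1))
  expect_equal(res$objective, sum(sort(ents)[1:2]), tolerance = 1e-12)
})

test_that("degenerate feature matrices are refused", {
  feats <- make_features()[, 1:4]
  feats[[3]] <- 1; feats[[4]] <- 2
  expect_error(collapse(feats), class = "lungchaos_collapse_infeasible_error")
})
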