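# Shared fixtures, generated in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

sine_samples <- function(freq, rate, duration, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  sin(2 * pi * freq * t + phase)
}

sine_recording <- function(freq = 50, rate = 4410L, duration = 10) {
  new_recording(0.9 * sine_samples(freq, rate, duration), rate,
                subject_id = "sine", site = "egophony")
}

logistic_map_orbit <- function(n, x0) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

henon_orbit <- function(n, a = 1.4, b = 0.3, x0 = 0.1, y0 = 0.1) {
  x <- numeric(n + 100); y <- numeric(n + 100)
  x[1] <- x0; y[1] <- y0
  for (i in 2:(n + 100)) {
    x[i] <- 1 - a * x[i - 1]^2 + y[i - 1]
    y[i] <- b * x[i - 1]
  }
  x[101:(n + 100)]
}

# Small pipeline configuration: 4 + 4 subjects, 2 s recordings, 24 portraits.
smoke_config <- function(master_seed = 11L) {
  pipeline_config(
    cohort = cohort_config(n_copd = 4L, n_control = 4L),
    acoustic = acoustic_config(duration = 2),
    library = portrait_library_config(
      bands = list(NULL, c(60, 600)),
      delays = c(1L, 2L, 4L, 8L, 12L, 16L, 24L),
      smoothings = c(3L, 5L, 9L),
      transforms = c("delay_pair", "derivative", "second_difference"),
      target_size = 22L
    ),
    master_seed = master_seed
  )
}

smoke_result <- function() {
  cached("smoke_result", run_pipeline(smoke_config(), chaos = FALSE))
}

# The packaged default study: 108 subjects, 216 recordings, full library.
# Computed once and shared by the acceptance tests (several minutes).
default_result <- function() {
  cached("default_result", run_pipeline(pipeline_config(), chaos = TRUE))
}

# A conditioned chaotic signal for estimator tests.
chaotic_samples <- function(seed = 5L, duration = 10) {
  cached(paste0("chaotic_samples_", seed, "_", duration), {
    rec <- withr::with_seed(seed, generate_recording(
      list(subject_id = "chaos", group = "COPD"),
      "egophony", acoustic_config(duration = duration, snr_db = Inf),
      envelope = "constant"
    ))
    preprocess(rec)$samples
  })
}
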