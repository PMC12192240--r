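# Synthetic two-site acoustic recordings.
#
# Each recording is the x-observable of a Roessler flow (a minimal,
# well-characterized low-dimensional chaotic system), run in a group-specific
# parameter regime, modulated by a site-specific breathing/phonation envelope,
# and measured with additive Gaussian noise. The class effect lives in the
# attractor geometry (the bifurcation parameter `c` differs by group), not in
# loudness or spectrum, so portrait-entropy features rather than amplitude
# carry the diagnostic signal.

#' Configuration of the synthetic acoustic generator
#'
#' @param wav_rate Output sampling rate in Hz (mobile-phone WAV standard).
#' @param analysis_rate Rate the analysis stages run at, Hz; `wav_rate` must be
#'   an integer multiple of it.
#' @param duration Recording length in seconds.
#' @param system_params_per_group Named list (`copd`, `control`) of Roessler
#'   parameters `a`, `b`, `c`. Both default regimes are chaotic; the groups
#'   differ only in the bifurcation parameter `c`, which changes the attractor
#'   geometry.
#' @param flow_rate Flow time units per second of audio. Together with the
#'   default parameters this places the orbital fundamental near 135 Hz, in
#'   the phonation band.
#' @param transient Flow time units discarded before sampling starts.
#' @param envelope_per_site Named list of envelope descriptors; see
#'   [site_envelope()]. Egophony is a repeated sustained-phonation
#'   (plateau-release) envelope; axillary is two tidal-breath cycles.
#' @param snr_db Measurement signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param peak_target Peak amplitude of the noise-free signal after
#'   normalization.
#' @param substeps RK4 integrator substeps per output sample.
#' @param seed Integer seed for the audio stream.
#' @return A list of class `lungchaos_acoustic_config`.
#' @export
acoustic_config <- function(wav_rate = 44100L,
                            analysis_rate = 4410L,
                            duration = 10,
                            system_params_per_group = list(
                              copd = c(a = 0.2, b = 0.2, c = 5.7),
                              control = c(a = 0.2, b = 0.2, c = 6.5)
                            ),
                            flow_rate = 800,
                            transient = 100,
                            envelope_per_site = list(
                              egophony = list(type = "phonation", breath_period = 4.3,
                                              rise = 0.15, release = 0.35, floor = 0.12),
                              axillary = list(type = "tidal", breath_period = 5,
                                              floor = 0.30)
                            ),
                            snr_db = 30,
                            peak_target = 0.95,
                            substeps = 1L,
                            seed = 1550L) {
  cfg <- list(
    wav_rate = as.integer(wav_rate), analysis_rate = as.integer(analysis_rate),
    duration = duration, system_params_per_group = system_params_per_group,
    flow_rate = flow_rate, transient = transient,
    envelope_per_site = envelope_per_site, snr_db = snr_db,
    peak_target = peak_target, substeps = as.integer(substeps),
    seed = as.integer(seed)
  )
  validate_acoustic_config(cfg)
  structure(cfg, class = "lungchaos_acoustic_config")
}

validate_acoustic_config <- function(cfg) {
  if (cfg$wav_rate <= 0L || cfg$analysis_rate <= 0L ||
      cfg$wav_rate %% cfg$analysis_rate != 0L) {
    stop_lungchaos("wav_rate must be a positive multiple of analysis_rate",
                   "lungchaos_config_error")
  }
  assert_number(cfg$duration, "duration", lower = 1e-3)
  assert_number(cfg$flow_rate, "flow_rate", lower = 1e-9)
  if (!is.finite(cfg$snr_db) && !identical(cfg$snr_db, Inf)) {
    stop_lungchaos("snr_db must be finite or +Inf", "lungchaos_config_error")
  }
  assert_number(cfg$peak_target, "peak_target", lower = 1e-6, upper = 1)
  for (g in c("copd", "control")) {
    p <- cfg$system_params_per_group[[g]]
    if (is.null(p) || !all(c("a", "b", "c") %in% names(p))) {
      stop_lungchaos(sprintf("missing Roessler parameters for group '%s'", g),
                     "lungchaos_config_error")
    }
  }
  for (s in c("egophony", "axillary")) {
    if (is.null(cfg$envelope_per_site[[s]])) {
      stop_lungchaos(sprintf("missing envelope for site '%s'", s),
                     "lungchaos_config_error")
    }
  }
  invisible(cfg)
}

#' Construct a recording object
#'
#' A recording is a mono time series tied to a subject and auscultation site,
#' with amplitudes in [-1, 1].
#'
#' @param samples Numeric vector of amplitudes in [-1, 1].
#' @param sample_rate Sampling rate, Hz.
#' @param subject_id,site Provenance metadata; `site` is `"egophony"` or
#'   `"axillary"`.
#' @return An object of class `lungchaos_recording`.
#' @export
new_recording <- function(samples, sample_rate, subject_id = NA_character_,
                          site = NA_character_) {
  if (sample_rate <= 0) {
    stop_lungchaos("sample_rate must be positive", "lungchaos_config_error")
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-12) {
    stop_lungchaos("recording amplitudes must lie in [-1, 1]",
                   "lungchaos_range_error")
  }
  structure(
    list(subject_id = subject_id, site = site,
         sample_rate = as.integer(sample_rate),
         samples = as.numeric(samples),
         duration = length(samples) / sample_rate),
    class = "lungchaos_recording"
  )
}

#' @export
print.lungchaos_recording <- function(x, ...) {
  cat(sprintf("<lungchaos_recording> subject=%s site=%s  %d samples @ %d Hz (%.2f s)\n",
              x$subject_id, x$site, length(x$samples), x$sample_rate, x$duration))
  invisible(x)
}

#' Site-specific amplitude envelope
#'
#' `"phonation"` produces repeated sustained-phonation cycles: a fast rise, a
#' plateau for most of the breath, and a release back to a low floor between
#' breaths (the egophony protocol: say "e" for one full breath, then repeat).
#' `"tidal"` produces smooth tidal-breathing cycles (two normal breaths over a
#' default 10 s recording). Envelopes never reach zero so the underlying
#' dynamics remain observable throughout.
#'
#' @param t Time points in seconds.
#' @param descriptor Envelope descriptor list (see [acoustic_config()]).
#' @return Numeric envelope values in (0, 1].
#' @export
site_envelope <- function(t, descriptor) {
  type <- descriptor$type
  period <- descriptor$breath_period
  floor_ <- descriptor$floor %||% 0.15
  phase <- t %% period
  if (identical(type, "phonation")) {
    rise <- descriptor$rise %||% 0.15
    release <- descriptor$release %||% 0.35
    plateau_end <- period - release
    env <- ifelse(
      phase < rise,
      floor_ + (1 - floor_) * phase / rise,
      ifelse(phase < plateau_end, 1,
             1 - (1 - floor_) * (phase - plateau_end) / release)
    )
    pmax(env, floor_)
  } else if (identical(type, "tidal")) {
    floor_ + (1 - floor_) * sin(pi * t / period)^2
  } else if (identical(type, "constant")) {
    rep(1, length(t))
  } else {
    stop_lungchaos(sprintf("unknown envelope type '%s'", type),
                   "lungchaos_config_error")
  }
}

# x-observable of the group's Roessler regime at the WAV rate.
flow_observable <- function(n, group, config) {
  p <- config$system_params_per_group[[if (group == "COPD") "copd" else "control"]]
  # randomized initial state; the transient pulls it onto the attractor
  x0 <- runif(1, -5, 5); y0 <- runif(1, -5, 5); z0 <- runif(1, 0, 2)
  dt <- config$flow_rate / config$wav_rate
  orbit <- rossler_orbit_cpp(n, dt, config$substeps,
                             p[["a"]], p[["b"]], p[["c"]],
                             x0, y0, z0, config$transient)
  orbit[, 1]
}

#' Generate one synthetic recording
#'
#' Produces the peak-normalized product of a group-specific chaotic-flow
#' observable and the site envelope, plus Gaussian measurement noise at the
#' configured SNR. Deterministic given the RNG state on entry (callers seed the
#' stream; [generate_dataset()] derives one stream per subject x site).
#'
#' @param subject One-row data frame (or list) with at least `subject_id` and
#'   `group`.
#' @param site `"egophony"` or `"axillary"`.
#' @param config An [acoustic_config()].
#' @param envelope Optional envelope override: `"site"` (default) uses the
#'   configured site envelope, `"constant"` disables modulation.
#' @return A [new_recording()] object at `config$wav_rate`.
#' @export
generate_recording <- function(subject, site = c("egophony", "axillary"),
                               config = acoustic_config(),
                               envelope = c("site", "constant")) {
  site <- match.arg(site)
  envelope <- match.arg(envelope)
  validate_acoustic_config(config)
  group <- as.character(subject$group)
  if (!group %in% c("COPD", "control")) {
    stop_lungchaos("subject$group must be 'COPD' or 'control'",
                   "lungchaos_config_error")
  }
  n <- as.integer(round(config$wav_rate * config$duration))
  x <- flow_observable(n, group, config)
  t <- (seq_len(n) - 1) / config$wav_rate
  desc <- if (envelope == "constant") list(type = "constant")
          else config$envelope_per_site[[site]]
  env <- site_envelope(t, desc)
  sig <- x * env
  peak <- max(abs(sig))
  if (peak > 0) sig <- sig * (config$peak_target / peak)
  if (is.finite(config$snr_db)) {
    noise_sd <- sqrt(mean(sig^2)) / 10^(config$snr_db / 20)
    sig <- sig + rnorm(n, 0, noise_sd)
    m <- max(abs(sig))
    if (m > 0.999) sig <- sig * (0.999 / m)
  }
  new_recording(sig, config$wav_rate, subject_id = subject$subject_id, site = site)
}

#' Generate a full synthetic dataset (cohort plus recordings)
#'
#' One master seed drives cohort sampling and every per-recording audio
#' stream, so repeated calls are bit-identical. Every subject gets exactly two
#' recordings, one per auscultation site.
#'
#' @param cohort_config A [cohort_config()].
#' @param acoustic_config An [acoustic_config()].
#' @param master_seed Optional master seed; defaults to `cohort_config$seed`.
#'   Per-subject, per-site audio seeds are derived from it.
#' @return A list with `subjects` (tibble, see [generate_cohort()]) and
#'   `recordings` (tibble with columns `subject_id`, `site`, `recording`
#'   list-column of [new_recording()] objects).
#' @export
generate_dataset <- function(cohort_config = lungchaos::cohort_config(),
                             acoustic_config = lungchaos::acoustic_config(),
                             master_seed = NULL) {
  master_seed <- master_seed %||% cohort_config$seed
  cohort_config$seed <- derive_seed(master_seed, "cohort")
  subjects <- generate_cohort(cohort_config)
  grid <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    site = c("egophony", "axillary")
  )
  recs <- purrr::pmap(grid, function(subject_id, site) {
    subj <- subjects[subjects$subject_id == subject_id, ]
    withr::with_seed(
      derive_seed(master_seed, "audio", subject_id, site),
      generate_recording(subj, site, acoustic_config)
    )
  })
  list(
    subjects = subjects,
    recordings = tibble::tibble(
      subject_id = grid$subject_id,
      site = grid$site,
      recording = recs
    )
  )
}
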