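# End-to-end orchestration: simulate -> condition -> featurize -> collapse ->
# fit -> evaluate, under one master seed.

#' Pipeline configuration
#'
#' Bundles every stage's configuration. A single `master_seed` fans out into
#' independent derived streams (cohort, each recording's audio, the split), so
#' stages are individually reproducible.
#'
#' @param cohort A [cohort_config()].
#' @param acoustic An [acoustic_config()].
#' @param preprocess A [preprocess_options()].
#' @param library A [portrait_library_config()].
#' @param binning A [binning_config()].
#' @param split_fraction Training fraction for the case-clustered split.
#' @param master_seed Master seed driving all randomness.
#' @return A list of class `lungchaos_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            acoustic = acoustic_config(),
                            preprocess = preprocess_options(),
                            library = portrait_library_config(),
                            binning = binning_config(),
                            split_fraction = 0.8,
                            master_seed = 1550L) {
  assert_number(split_fraction, "split_fraction", lower = 1e-9, upper = 1 - 1e-9)
  if (cohort$n_copd < 1L || cohort$n_control < 1L) {
    stop_lungchaos("classification needs both classes: n_copd and n_control must be >= 1",
                   "lungchaos_config_error")
  }
  structure(
    list(cohort = cohort, acoustic = acoustic, preprocess = preprocess,
         library = library, binning = binning,
         split_fraction = split_fraction,
         master_seed = as.integer(master_seed)),
    class = "lungchaos_pipeline_config"
  )
}

#' Validate a JSON pipeline configuration file
#'
#' Reads a (possibly partial) JSON config, rejects unknown keys, fills
#' defaults, and checks every invariant. An empty file yields the full default
#' configuration.
#'
#' @param path JSON file path.
#' @return A validated [pipeline_config()].
#' @export
validate_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nchar(trimws(txt)) == 0) list() else jsonlite::parse_json(txt)
  known <- c("cohort", "acoustic", "preprocess", "library", "binning",
             "split_fraction", "master_seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_lungchaos(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                   "lungchaos_config_error")
  }
  build <- function(ctor, overrides) {
    if (is.null(overrides)) return(ctor())
    defaults <- formals(ctor)
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop_lungchaos(sprintf("unknown field(s): %s", paste(bad, collapse = ", ")),
                     "lungchaos_config_error")
    }
    do.call(ctor, overrides)
  }
  pipeline_config(
    cohort = build(cohort_config, raw$cohort),
    acoustic = build(acoustic_config, raw$acoustic),
    preprocess = build(preprocess_options, raw$preprocess),
    library = build(portrait_library_config, raw$library),
    binning = build(binning_config, raw$binning),
    split_fraction = raw$split_fraction %||% 0.8,
    master_seed = raw$master_seed %||% 1550L
  )
}

# Downstream stages shared by run_pipeline() and run_analyze():
# per-recording conditioning + featurization (+ chaos), then collapse, split,
# fits and reports. `get_recording(subject_id, site)` must return a
# lungchaos_recording.
run_analysis_stages <- function(subjects, get_recording, config,
                                chaos = TRUE, verbose = FALSE) {
  library_tbl <- build_library(config$library)
  sites <- c("egophony", "axillary")
  features <- list(); chaos_rows <- list()
  for (site in sites) {
    rows <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]
      rec <- get_recording(sid, site)
      conditioned <- preprocess(rec, config$preprocess)
      rows[[i]] <- featurize_samples(conditioned$samples, conditioned$sample_rate,
                                     library_tbl, config$binning,
                                     max_samples = 16384L)
      if (chaos) {
        chaos_rows[[length(chaos_rows) + 1L]] <-
          chaos_from_samples(conditioned$samples, subject_id = sid, site = site)
      }
      if (verbose && i %% 20 == 0) {
        message(sprintf("[%s] featurized %d/%d", site, i, nrow(subjects)))
      }
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- sprintf("p%03d", library_tbl$portrait_id)
    features[[site]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = subjects$subject_id, site = site),
      tibble::as_tibble(mat)
    )
  }
  chaos_tbl <- if (chaos) {
    ct <- dplyr::bind_rows(chaos_rows)
    class(ct) <- c("lungchaos_chaos", class(ct))
    ct
  }
  coords <- purrr::map(features, collapse, binning = config$binning)
  labels <- subjects[, c("subject_id", "group")]
  split <- split_cases(subjects$subject_id, config$split_fraction,
                       seed = derive_seed(config$master_seed, "split"))
  models <- list(
    egophony = fit_site_model(coords$egophony, labels, split),
    axillary = fit_site_model(coords$axillary, labels, split),
    composite = fit_composite(coords$egophony, coords$axillary, labels, split)
  )
  reports <- evaluate_models(models, coords, labels, split)
  probs <- attr(reports, "probabilities")
  composite_preds <- probs[probs$model == "composite", ]
  subgroups <- subgroup_accuracy(composite_preds, subjects)
  structure(
    list(subjects = subjects, features = features, collapse = coords,
         chaos = chaos_tbl, split = split, models = models, reports = reports,
         subgroup_accuracy = subgroups,
         group_comparisons = compare_groups(subjects),
         config = config),
    class = "lungchaos_result"
  )
}

#' Run the full synthetic-study pipeline
#'
#' Generates the cohort and per-subject two-site recordings, conditions and
#' featurizes each recording, computes the chaos diagnostics, collapses the
#' feature matrices per site, fits per-site and composite classifiers on the
#' train side of the case-clustered split, and evaluates everything. All
#' randomness derives from `config$master_seed`; two runs with the same
#' configuration give identical numeric results.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for report artifacts (CSV/JSON);
#'   `NULL` keeps everything in memory.
#' @param write_audio Also write the WAV dataset under `output_dir/audio`.
#' @param chaos Compute per-recording chaos diagnostics (the slowest stage).
#' @param verbose Progress messages to stderr.
#' @return An object of class `lungchaos_result` with elements `subjects`,
#'   `features`, `collapse`, `chaos`, `split`, `models`, `reports`,
#'   `subgroup_accuracy`, `group_comparisons`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         write_audio = FALSE, chaos = TRUE, verbose = FALSE) {
  master <- config$master_seed
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(master, "cohort")
  subjects <- generate_cohort(cohort_cfg)
  audio_dir <- if (!is.null(output_dir) && write_audio) {
    d <- file.path(output_dir, "audio")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  manifest_entries <- list()
  get_recording <- function(sid, site) {
    subj <- subjects[subjects$subject_id == sid, ]
    rec <- withr::with_seed(
      derive_seed(master, "audio", sid, site),
      generate_recording(subj, site, config$acoustic)
    )
    if (!is.null(audio_dir)) {
      fname <- sprintf("%s_%s.wav", sid, site)
      write_wav(rec, file.path(audio_dir, fname))
      manifest_entries[[length(manifest_entries) + 1L]] <<-
        list(subject_id = sid, site = site, file = fname,
             sample_rate = rec$sample_rate, duration = rec$duration)
    }
    rec
  }
  result <- run_analysis_stages(subjects, get_recording, config,
                                chaos = chaos, verbose = verbose)
  if (!is.null(audio_dir)) {
    readr::write_csv(subjects, file.path(audio_dir, "cohort.csv"))
    jsonlite::write_json(
      list(master_seed = master, cohort_csv = "cohort.csv",
           recordings = manifest_entries),
      file.path(audio_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  if (!is.null(output_dir)) write_result(result, output_dir)
  result
}

#' Analyze an externally supplied WAV dataset
#'
#' Entry point for real recordings: reads a directory written in the package's
#' dataset layout (`manifest.json`, `cohort.csv`, one mono WAV per subject and
#' site) and runs every stage downstream of simulation. Each subject must have
#' both an egophony and an axillary recording.
#'
#' @param wav_dir Dataset directory (see [write_dataset()]).
#' @param config A [pipeline_config()]; the cohort/acoustic sub-configs are
#'   ignored in favor of the files on disk.
#' @param output_dir,chaos,verbose As in [run_pipeline()].
#' @return A `lungchaos_result`.
#' @export
run_analyze <- function(wav_dir, config = pipeline_config(), output_dir = NULL,
                        chaos = TRUE, verbose = FALSE) {
  ds <- read_dataset(wav_dir)
  subjects <- ds$subjects
  if (!"group" %in% names(subjects) || any(is.na(subjects$group)) ||
      !all(subjects$group %in% c("COPD", "control"))) {
    stop_lungchaos("cohort.csv must label every subject 'COPD' or 'control'",
                   "lungchaos_config_error")
  }
  for (site in c("egophony", "axillary")) {
    have <- ds$recordings$subject_id[ds$recordings$site == site]
    missing <- setdiff(subjects$subject_id, have)
    if (length(missing)) {
      stop_lungchaos(
        sprintf("missing %s recording(s) for subject(s): %s",
                site, paste(missing, collapse = ", ")),
        "lungchaos_coverage_error"
      )
    }
  }
  get_recording <- function(sid, site) {
    ds$recordings$recording[[which(ds$recordings$subject_id == sid &
                                     ds$recordings$site == site)[1]]]
  }
  result <- run_analysis_stages(subjects, get_recording, config,
                                chaos = chaos, verbose = verbose)
  if (!is.null(output_dir)) write_result(result, output_dir)
  result
}

# Serialize every report artifact as CSV/JSON under `dir`.
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$subjects, file.path(dir, "cohort.csv"))
  for (site in names(result$features)) {
    readr::write_csv(result$features[[site]],
                     file.path(dir, sprintf("features_%s.csv", site)))
  }
  if (!is.null(result$chaos)) {
    readr::write_csv(
      dplyr::select(result$chaos, -"divergence_curve", -"correlation_curve"),
      file.path(dir, "chaos_metrics.csv")
    )
  }
  readr::write_csv(result$reports, file.path(dir, "confusion_reports.csv"))
  readr::write_csv(result$subgroup_accuracy, file.path(dir, "subgroup_accuracy.csv"))
  readr::write_csv(result$group_comparisons, file.path(dir, "group_comparisons.csv"))
  readr::write_csv(result$split, file.path(dir, "split.csv"))
  jsonlite::write_json(
    list(
      collapse = purrr::map(result$collapse, function(cl) {
        list(site = cl$site, selected = cl$selected_portraits,
             objective = cl$objective, method = cl$search_method)
      }),
      models = purrr::map(result$models, function(m) {
        list(intercept = m$intercept, coefficients = as.list(m$coefficients),
             feature_means = as.list(m$feature_means),
             feature_sds = as.list(m$feature_sds), ridge = m$ridge,
             converged = m$converged, n_iter = m$n_iter)
      }),
      split = list(seed = attr(result$split, "seed"),
                   fraction = attr(result$split, "fraction")),
      master_seed = result$config$master_seed,
      config_hash = rlang::hash(result$config)
    ),
    file.path(dir, "analysis_manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.lungchaos_result <- function(x, ...) {
  comp <- x$reports[x$reports$model == "composite", ]
  cat(sprintf("<lungchaos_result> %d subjects (%d COPD / %d control)\n",
              nrow(x$subjects), sum(x$subjects$group == "COPD"),
              sum(x$subjects$group == "control")))
  cat(sprintf("  composite AUC: train %.3f, test %.3f\n",
              comp$auc[comp$side == "train"], comp$auc[comp$side == "test"]))
  if (!is.null(x$chaos)) {
    cat(sprintf("  chaos: max Dcorr %.2f, min MLE %.4f nats/sample (%d recordings)\n",
                max(x$chaos$dcorr), min(x$chaos$mle), nrow(x$chaos)))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `lungchaos_result`.
#' @param ... Ignored.
#' @export
tidy.lungchaos_result <- function(x, ...) {
  tibble::as_tibble(x$reports)
}

#' @rdname run_pipeline
#' @export
glance.lungchaos_result <- function(x, ...) {
  comp <- x$reports[x$reports$model == "composite", ]
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_recordings = if (is.null(x$chaos)) NA_integer_ else nrow(x$chaos),
    composite_train_auc = comp$auc[comp$side == "train"],
    composite_test_auc = comp$auc[comp$side == "test"],
    max_dcorr = if (is.null(x$chaos)) NA_real_ else max(x$chaos$dcorr),
    min_mle = if (is.null(x$chaos)) NA_real_ else min(x$chaos$mle),
    min_subgroup_test_accuracy =
      min(x$subgroup_accuracy$test_accuracy, na.rm = TRUE)
  )
}
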