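# WAV input/output (RIFF, mono, 16-bit PCM) and dataset serialization.
#
# Subject/site metadata travels in a JSON manifest next to the WAV files, not
# in WAV tags, for portability across recording apps.

#' Write a recording as a mono 16-bit PCM WAV file
#'
#' @param recording A [new_recording()] object with amplitudes in [-1, 1];
#'   out-of-range amplitudes raise an error rather than being clipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  x <- recording$samples
  if (length(x) && max(abs(x)) > 1) {
    stop_lungchaos("amplitudes outside [-1, 1]; refusing to clip",
                   "lungchaos_range_error")
  }
  pcm <- as.integer(round(x * 32767))
  pcm <- pmax(pmin(pcm, 32767L), -32768L)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(recording$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(recording$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @param subject_id,site Optional metadata to attach (usually supplied from a
#'   dataset manifest).
#' @return A [new_recording()] with samples scaled to [-1, 1].
#' @export
read_wav <- function(path, subject_id = NA_character_, site = NA_character_) {
  if (!file.exists(path)) {
    stop_lungchaos(sprintf("no such file: %s", path), "lungchaos_io_error")
  }
  size <- file.info(path)$size
  if (is.na(size) || size < 44) {
    stop_lungchaos(sprintf("malformed WAV (too short): %s", path),
                   "lungchaos_malformed_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_lungchaos(sprintf("not a RIFF/WAVE file: %s", path),
                   "lungchaos_malformed_error")
  }
  sample_rate <- NULL; channels <- NULL; bits <- NULL; fmt_code <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      stop_lungchaos(sprintf("no data chunk found: %s", path),
                     "lungchaos_malformed_error")
    }
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- chunk_size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) {
        stop_lungchaos("data chunk precedes fmt chunk", "lungchaos_malformed_error")
      }
      if (fmt_code != 1L || bits != 16L) {
        stop_lungchaos("unsupported format: only 16-bit PCM is supported",
                       "lungchaos_unsupported_format_error")
      }
      if (channels != 1L) {
        stop_lungchaos("unsupported format: only mono recordings are supported",
                       "lungchaos_unsupported_format_error")
      }
      pcm <- readBin(con, "integer", chunk_size / 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(new_recording(pcm / 32767, sample_rate,
                           subject_id = subject_id, site = site))
    } else {
      if (chunk_size < 0) {
        stop_lungchaos("malformed chunk size", "lungchaos_malformed_error")
      }
      readBin(con, "raw", chunk_size + (chunk_size %% 2L))
    }
  }
}

#' Write a synthetic dataset to disk
#'
#' Writes one WAV per recording, the cohort as CSV (one row per subject), and
#' a JSON manifest tying subject ids and sites to file paths and recording the
#' seeds in play.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param master_seed Seed recorded in the manifest for provenance.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, master_seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$subjects, file.path(dir, "cohort.csv"))
  entries <- purrr::pmap(dataset$recordings, function(subject_id, site, recording) {
    fname <- sprintf("%s_%s.wav", subject_id, site)
    write_wav(recording, file.path(dir, fname))
    list(subject_id = subject_id, site = site, file = fname,
         sample_rate = recording$sample_rate, duration = recording$duration)
  })
  manifest <- list(
    master_seed = master_seed,
    cohort_csv = "cohort.csv",
    recordings = entries
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.json`, `cohort.csv` and the WAVs.
#' @return A list with `subjects` and `recordings`, shaped like
#'   [generate_dataset()] output.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_lungchaos(sprintf("no manifest.json in %s", dir), "lungchaos_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path)
  subjects <- readr::read_csv(file.path(dir, manifest$cohort_csv),
                              show_col_types = FALSE)
  recs <- purrr::map(manifest$recordings, function(e) {
    p <- file.path(dir, e$file)
    if (!file.exists(p)) {
      stop_lungchaos(
        sprintf("missing %s recording for subject %s (%s)", e$site, e$subject_id, p),
        "lungchaos_coverage_error"
      )
    }
    read_wav(p, subject_id = e$subject_id, site = e$site)
  })
  list(
    subjects = subjects,
    recordings = tibble::tibble(
      subject_id = purrr::map_chr(manifest$recordings, "subject_id"),
      site = purrr::map_chr(manifest$recordings, "site"),
      recording = recs
    )
  )
}
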