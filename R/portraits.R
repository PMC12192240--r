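# The open portrait library.
#
# The study's portrait identities are proprietary; this package replaces them
# with a documented, deterministic grid of band-pass filters x transforms x
# delays, pegged to at least 300 entries. Each spec maps a conditioned signal
# to a two-dimensional point set highlighting one view of the dynamics.

portrait_transforms <- c("delay_pair", "derivative", "second_difference")

#' Portrait-library configuration
#'
#' The default grid enumerates 10 frequency bands (including broadband)
#' crossed with 27 delay-pair lags, 4 derivative smoothing windows and one
#' second-difference transform: 320 cells, truncated to the 300-portrait
#' target.
#'
#' @param bands List of band edges in Hz (`NULL` = broadband).
#' @param delays Integer lags (samples) for the delay-pair transform.
#' @param smoothings Moving-average windows (samples) for the derivative
#'   transform.
#' @param transforms Subset of `c("delay_pair", "derivative",
#'   "second_difference")`.
#' @param target_size Number of portraits kept from the enumerated grid.
#' @return A list of class `lungchaos_library_config`.
#' @export
portrait_library_config <- function(bands = list(
                                      NULL, c(30, 300), c(60, 600), c(100, 400),
                                      c(150, 900), c(250, 1250), c(400, 1600),
                                      c(700, 2000), c(40, 150), c(90, 180)
                                    ),
                                    delays = c(1:16, 18L, 20L, 22L, 24L, 28L,
                                               32L, 36L, 40L, 48L, 56L, 64L),
                                    smoothings = c(3L, 5L, 9L, 15L),
                                    transforms = portrait_transforms,
                                    target_size = 300L) {
  if (!length(bands) || !length(transforms)) {
    stop_lungchaos("bands and transforms must be nonempty", "lungchaos_config_error")
  }
  if (!all(transforms %in% portrait_transforms)) {
    stop_lungchaos("unknown transform name", "lungchaos_config_error")
  }
  structure(
    list(bands = bands, delays = as.integer(delays),
         smoothings = as.integer(smoothings),
         transforms = transforms, target_size = as.integer(target_size)),
    class = "lungchaos_library_config"
  )
}

#' Enumerate the portrait library
#'
#' Deterministically enumerates band x transform x parameter cells in a fixed
#' order (bands outermost, then delay-pair lags, derivative smoothings, and
#' the second difference), truncates to `target_size`, and assigns ids
#' `0..target_size - 1`. Two calls with the same config produce identical
#' libraries.
#'
#' @param config A [portrait_library_config()].
#' @return A tibble of portrait specs: `portrait_id`, `band_low`, `band_high`
#'   (Hz, `NA` = broadband), `transform`, `delay`, `smoothing`.
#' @export
build_library <- function(config = portrait_library_config()) {
  rows <- list()
  for (b in config$bands) {
    lo <- if (is.null(b)) NA_real_ else b[1]
    hi <- if (is.null(b)) NA_real_ else b[2]
    if ("delay_pair" %in% config$transforms) {
      for (d in config$delays) {
        rows[[length(rows) + 1L]] <- list(band_low = lo, band_high = hi,
                                          transform = "delay_pair",
                                          delay = d, smoothing = NA_integer_)
      }
    }
    if ("derivative" %in% config$transforms) {
      for (s in config$smoothings) {
        rows[[length(rows) + 1L]] <- list(band_low = lo, band_high = hi,
                                          transform = "derivative",
                                          delay = NA_integer_, smoothing = s)
      }
    }
    if ("second_difference" %in% config$transforms) {
      rows[[length(rows) + 1L]] <- list(band_low = lo, band_high = hi,
                                        transform = "second_difference",
                                        delay = NA_integer_,
                                        smoothing = NA_integer_)
    }
  }
  if (length(rows) < config$target_size) {
    stop_lungchaos(
      sprintf("library grid has %d cells but target_size is %d",
              length(rows), config$target_size),
      "lungchaos_library_too_small_error"
    )
  }
  lib <- dplyr::bind_rows(rows)[seq_len(config$target_size), ]
  dplyr::mutate(lib, portrait_id = dplyr::row_number() - 1L, .before = 1)
}

# Band-pass a conditioned signal for one portrait spec (NA band = passthrough).
portrait_filter <- function(samples, band_low, band_high, rate) {
  if (is.na(band_low)) return(samples)
  nyq <- rate / 2
  if (band_high >= nyq || band_low <= 0 || band_low >= band_high) {
    stop_lungchaos("portrait band must satisfy 0 < low < high < Nyquist",
                   "lungchaos_spec_error")
  }
  fir_filter(samples, c(band_low, band_high) / nyq, order = 256L, type = "pass")
}

# Transform a (filtered) signal into 2-D points per the spec row.
portrait_points <- function(samples, spec) {
  n <- length(samples)
  switch(spec$transform,
    delay_pair = {
      tau <- spec$delay
      if (n <= tau) {
        stop_lungchaos("signal too short for delay-pair portrait",
                       "lungchaos_length_error")
      }
      cbind(x = samples[1:(n - tau)], y = samples[(tau + 1):n])
    },
    derivative = derivative_portrait(samples, spec$smoothing),
    second_difference = {
      if (n < 3L) {
        stop_lungchaos("signal too short for second-difference portrait",
                       "lungchaos_length_error")
      }
      i <- 2:(n - 1L)
      cbind(x = samples[i], y = samples[i + 1L] - 2 * samples[i] + samples[i - 1L])
    },
    stop_lungchaos(sprintf("unknown transform '%s'", spec$transform),
                   "lungchaos_spec_error")
  )
}

#' Apply one portrait spec to a signal
#'
#' Optionally band-passes the signal, applies the spec's transform, and
#' returns the finite 2-D point set.
#'
#' @param samples Numeric vector (a conditioned recording's samples).
#' @param spec One row of a [build_library()] tibble (or an equivalent list).
#' @param rate Sampling rate of `samples` in Hz.
#' @param recording_id Optional provenance tag.
#' @return An object of class `lungchaos_portrait` with fields `points`
#'   (n x 2 matrix), `spec` and `recording_id`.
#' @export
apply_portrait <- function(samples, spec, rate, recording_id = NA_character_) {
  spec <- as.list(spec)
  filtered <- portrait_filter(samples, spec$band_low, spec$band_high, rate)
  pts <- portrait_points(filtered, spec)
  keep <- is.finite(pts[, 1]) & is.finite(pts[, 2])
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 100L) {
    stop_lungchaos("portrait has fewer than 100 finite points",
                   "lungchaos_length_error")
  }
  structure(list(points = pts, spec = spec, recording_id = recording_id),
            class = "lungchaos_portrait")
}

#' @export
print.lungchaos_portrait <- function(x, ...) {
  band <- if (is.na(x$spec$band_low)) "broadband"
          else sprintf("%g-%g Hz", x$spec$band_low, x$spec$band_high)
  cat(sprintf("<lungchaos_portrait> %s, %s, %d points\n",
              x$spec$transform, band, nrow(x$points)))
  invisible(x)
}

#' @rdname apply_portrait
#' @param object A `lungchaos_portrait`.
#' @param ... Ignored.
#' @export
autoplot.lungchaos_portrait <- function(object, ...) {
  df <- tibble::tibble(x = object$points[, 1], y = object$points[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.35) +
    ggplot2::labs(
      x = "amplitude", y = "transform coordinate",
      title = sprintf("%s portrait", object$spec$transform)
    ) +
    ggplot2::theme_minimal()
}
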