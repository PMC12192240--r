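# Nonlinear-dynamics validation: maximal Lyapunov exponent (Rosenstein) and
# correlation dimension (Grassberger-Procaccia).
#
# Units: the MLE is reported in nats per sample at the analysis rate;
# multiply by the sample rate for nats per second. Both estimators are fully
# deterministic (fixed subsampling strides, no RNG).

#' Rosenstein maximal Lyapunov exponent
#'
#' Embeds the signal, pairs a deterministic subsample of reference points with
#' their nearest neighbours outside the Theiler window, follows both
#' trajectories forward, and fits a least-squares line to the mean log
#' separation versus time offset. A positive slope indicates exponential
#' divergence of nearby trajectories, the operational signature of chaos.
#'
#' @param samples Numeric vector.
#' @param embedding An [embedding_config()].
#' @param theiler Temporal exclusion window in samples (>= delay).
#' @param fit_window Integer range of divergence-curve offsets used for the
#'   slope fit; defaults to `1:(delay * dimension)`.
#' @param max_points Maximum number of reference points (deterministic evenly
#'   spaced subsample).
#' @param max_candidates Cap on the neighbour-candidate grid (deterministic
#'   stride over all embedded points).
#' @return A list with `mle` (nats/sample), `fit_r2`, `divergence_curve`
#'   (tibble: `offset`, `mean_log_distance`) and `n_pairs`.
#' @export
max_lyapunov <- function(samples, embedding, theiler = NULL,
                         fit_window = NULL, max_points = 400L,
                         max_candidates = 12000L) {
  theiler <- theiler %||% (2L * embedding$delay)
  emb <- delay_embed(samples, embedding)
  n <- nrow(emb)
  kmax_default <- embedding$delay * embedding$dimension
  fit_window <- fit_window %||% seq_len(kmax_default)
  kmax <- max(fit_window)
  if (n - 1L - kmax < 10L) {
    stop_lungchaos("too few embedded points for the requested fit window",
                   "lungchaos_insufficient_data_error")
  }
  last <- n - 1L - kmax
  refs <- unique(as.integer(round(seq(0L, last, length.out = min(max_points, last + 1L)))))
  cand_stride <- max(1L, as.integer(ceiling((last + 1L) / max_candidates)))
  res <- rosenstein_divergence_cpp(emb, refs, as.integer(theiler),
                                   as.integer(kmax), cand_stride)
  if (res$n_pairs == 0L || all(!is.finite(res$curve))) {
    stop_lungchaos("no valid neighbour pairs (degenerate signal?)",
                   "lungchaos_insufficient_data_error")
  }
  curve <- tibble::tibble(offset = 0:kmax, mean_log_distance = res$curve)
  keep <- fit_window[is.finite(res$curve[fit_window + 1L])]
  if (length(keep) < 2L) {
    stop_lungchaos("divergence curve too sparse over the fit window",
                   "lungchaos_insufficient_data_error")
  }
  fit <- stats::lm.fit(cbind(1, keep), res$curve[keep + 1L])
  y <- res$curve[keep + 1L]
  r2 <- if (var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  list(mle = unname(fit$coefficients[2]), fit_r2 = max(0, min(1, r2)),
       divergence_curve = curve, n_pairs = res$n_pairs)
}

# Default geometric radius grid: spans about 1.6 decades relative to the
# signal's standard deviation, starting above typical measurement-noise
# scales so the fit sees attractor scaling rather than the noise ball.
default_radii <- function(samples) {
  s <- sd(samples)
  s * exp(seq(log(0.07), log(2.8), length.out = 20))
}

#' Grassberger-Procaccia correlation dimension
#'
#' Computes the correlation sum C(r) (fraction of Theiler-admissible point
#' pairs within distance r) on a geometric radius grid and estimates the
#' dimension as the slope of log C versus log r over the contiguous window
#' (at least `min_window` radii) that maximizes the linear-fit R-squared,
#' restricted to the band `C(r)` in `[1e-4, 1e-1]` where the scaling regime
#' lives at desk-scale point counts.
#'
#' @inheritParams max_lyapunov
#' @param radii Increasing radius grid; defaults to 20 geometric points
#'   spanning 0.07-2.8 signal standard deviations.
#' @param max_points Deterministic subsample size for the pair sums.
#' @param min_window Minimum radii per candidate fit window.
#' @return A list with `dcorr`, `fit_r2`, `fit_range` (radii), and
#'   `correlation_curve` (tibble: `radius`, `c_r`).
#' @export
correlation_dimension <- function(samples, embedding, theiler = NULL,
                                  radii = NULL, max_points = 1500L,
                                  min_window = 5L) {
  theiler <- theiler %||% (2L * embedding$delay)
  radii <- radii %||% default_radii(samples)
  if (length(radii) < 8L || is.unsorted(radii)) {
    stop_lungchaos("need >= 8 increasing radii", "lungchaos_config_error")
  }
  emb <- delay_embed(samples, embedding)
  n <- nrow(emb)
  if (n < 500L) {
    stop_lungchaos("need >= 500 embedded points", "lungchaos_insufficient_data_error")
  }
  stride <- max(1L, as.integer(ceiling(n / max_points)))
  idx <- seq.int(1L, n, by = stride)
  res <- correlation_counts_cpp(emb[idx, , drop = FALSE], as.integer(idx - 1L),
                                as.numeric(radii), as.integer(theiler))
  if (res$n_pairs == 0) {
    stop_lungchaos("no admissible point pairs", "lungchaos_insufficient_data_error")
  }
  c_r <- res$counts / res$n_pairs
  curve <- tibble::tibble(radius = radii, c_r = c_r)
  admissible <- which(c_r >= 1e-4 & c_r <= 1e-1)
  best <- NULL
  nr <- length(radii)
  for (a in seq_len(nr)) {
    for (b in seq_len(nr)) {
      if (b - a + 1L < min_window) next
      win <- a:b
      if (!all(win %in% admissible)) next
      lx <- log(radii[win]); ly <- log(c_r[win])
      fit <- stats::lm.fit(cbind(1, lx), ly)
      r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
      if (is.null(best) || r2 > best$r2) {
        best <- list(slope = unname(fit$coefficients[2]), r2 = r2, win = win)
      }
    }
  }
  if (is.null(best)) {
    stop_lungchaos("no scaling region: C(r) never stays within [1e-4, 1e-1]",
                   "lungchaos_scaling_region_error")
  }
  list(dcorr = best$slope, fit_r2 = max(0, min(1, best$r2)),
       fit_range = range(radii[best$win]), correlation_curve = curve)
}

#' Chaos diagnostics for one recording
#'
#' Conditions the recording, chooses the embedding delay from the data (first
#' minimum of the average mutual information) unless an embedding is supplied,
#' and runs both estimators with a shared Theiler window of twice the delay.
#'
#' @param recording A [new_recording()] object.
#' @param opts A [preprocess_options()].
#' @param embedding Optional [embedding_config()]; by default dimension 5 with
#'   the data-chosen delay.
#' @return A one-row tibble: `subject_id`, `site`, `mle`, `mle_fit_r2`,
#'   `dcorr`, `dcorr_fit_r2`, `delay`, `dimension`, `theiler`, plus
#'   list-columns `divergence_curve` and `correlation_curve`.
#' @export
chaos_summary <- function(recording, opts = preprocess_options(),
                          embedding = NULL) {
  conditioned <- preprocess(recording, opts)
  tryCatch(
    chaos_from_samples(conditioned$samples, embedding,
                       subject_id = recording$subject_id, site = recording$site),
    lungchaos_error = function(e) {
      stop_lungchaos(
        sprintf("chaos estimation failed for %s/%s: %s",
                recording$subject_id, recording$site, conditionMessage(e)),
        class(e)[1]
      )
    }
  )
}

# Shared worker: estimators on already-conditioned samples.
chaos_from_samples <- function(samples, embedding = NULL,
                               subject_id = NA_character_,
                               site = NA_character_) {
  if (is.null(embedding)) {
    tau <- select_delay(samples)
    embedding <- embedding_config(delay = tau, dimension = 5L)
  }
  theiler <- 2L * embedding$delay
  ly <- max_lyapunov(samples, embedding, theiler)
  cd <- correlation_dimension(samples, embedding, theiler)
  tibble::tibble(
    subject_id = subject_id, site = site,
    mle = ly$mle, mle_fit_r2 = ly$fit_r2,
    dcorr = cd$dcorr, dcorr_fit_r2 = cd$fit_r2,
    delay = embedding$delay, dimension = embedding$dimension, theiler = theiler,
    divergence_curve = list(ly$divergence_curve),
    correlation_curve = list(cd$correlation_curve)
  )
}

#' Chaos diagnostics for every recording in a dataset
#'
#' @param recordings Tibble with `subject_id`, `site` and a `recording`
#'   list-column (as produced by [generate_dataset()] or [read_dataset()]).
#' @param opts A [preprocess_options()].
#' @param embedding Optional shared [embedding_config()].
#' @return A tibble with one row per recording (see [chaos_summary()]),
#'   classed `lungchaos_chaos` for plotting.
#' @export
chaos_table <- function(recordings, opts = preprocess_options(),
                        embedding = NULL) {
  rows <- purrr::pmap(recordings, function(subject_id, site, recording, ...) {
    chaos_summary(recording, opts, embedding)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lungchaos_chaos", class(out))
  out
}

#' Plot the MLE-versus-Dcorr map of a dataset
#'
#' Scatter of maximal Lyapunov exponent against correlation dimension for all
#' recordings, colored by auscultation site; recordings in the chaotic
#' low-dimensional regime sit right of zero and below the dimension guide.
#'
#' @param object A [chaos_table()] result.
#' @param dcorr_guide Horizontal guide line (dimension bound of interest).
#' @param ... Ignored.
#' @export
autoplot.lungchaos_chaos <- function(object, dcorr_guide = 2.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mle, y = .data$dcorr,
                                       color = .data$site)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = dcorr_guide, linetype = "dotted") +
    ggplot2::labs(x = "maximal Lyapunov exponent (nats/sample)",
                  y = "correlation dimension") +
    ggplot2::theme_minimal()
}
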