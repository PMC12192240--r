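# Occupancy-entropy features and the entropic collapse to two dimensions.
#
# Each recording becomes a vector of per-portrait Shannon occupancy entropies
# (a complexity descriptor of the attractor geometry, invariant to amplitude
# scaling because the histogram is robust-range binned). The cohort's
# recordings x portraits matrix is then collapsed, without ever consulting
# labels, by selecting the column pair with minimal standardized-histogram
# entropy: after standardization, equal-width-bin entropy is lowest for
# clustered/bimodal columns, exactly the structure-bearing features.

#' Histogram configuration for the entropy stages
#'
#' @param nx,ny Occupancy grid for 2-D portraits, spanning the robust
#'   (1st-99th percentile) range per axis; points outside are clamped to the
#'   edge cells.
#' @param column_bins Equal-width bins on the standardized range [-3, 3] used
#'   for feature-column entropies (outliers go to the edge bins).
#' @return A list of class `lungchaos_binning`.
#' @export
binning_config <- function(nx = 32L, ny = 32L, column_bins = 16L) {
  if (nx < 4L || ny < 4L || column_bins < 4L) {
    stop_lungchaos("all bin counts must be >= 4", "lungchaos_config_error")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 column_bins = as.integer(column_bins)),
            class = "lungchaos_binning")
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Entropy of a 2-D point set on the robust-range occupancy grid.
points_occupancy_entropy <- function(pts, binning) {
  qx <- quantile(pts[, 1], c(0.01, 0.99), names = FALSE, type = 7)
  qy <- quantile(pts[, 2], c(0.01, 0.99), names = FALSE, type = 7)
  if (qx[1] == qx[2] || qy[1] == qy[2]) {
    return(structure(0, degenerate = TRUE))
  }
  bx <- seq(qx[1], qx[2], length.out = binning$nx + 1L)
  by <- seq(qy[1], qy[2], length.out = binning$ny + 1L)
  ix <- pmin(pmax(findInterval(pts[, 1], bx, all.inside = TRUE), 1L), binning$nx)
  iy <- pmin(pmax(findInterval(pts[, 2], by, all.inside = TRUE), 1L), binning$ny)
  counts <- tabulate((iy - 1L) * binning$nx + ix, nbins = binning$nx * binning$ny)
  structure(shannon_bits(counts / nrow(pts)), degenerate = FALSE)
}

#' Shannon occupancy entropy of a portrait
#'
#' Entropy (bits) of the portrait's 2-D occupancy histogram. A tight periodic
#' orbit occupies few cells and scores low; a space-filling attractor scores
#' high. Degenerate portraits (all points identical on an axis) return 0 with
#' a `degenerate` attribute.
#'
#' @param portrait A [apply_portrait()] result (or any object with a `points`
#'   matrix).
#' @param binning A [binning_config()].
#' @return Entropy in bits, in `[0, log2(nx * ny)]`.
#' @export
occupancy_entropy <- function(portrait, binning = binning_config()) {
  pts <- if (is.matrix(portrait)) portrait else portrait$points
  if (nrow(pts) < 100L) {
    stop_lungchaos("portrait has fewer than 100 points", "lungchaos_length_error")
  }
  points_occupancy_entropy(pts, binning)
}

# Fast featurization worker on conditioned samples: filters once per band and
# reuses the filtered signal across that band's portraits.
featurize_samples <- function(samples, rate, library, binning, max_samples) {
  if (length(samples) > max_samples) samples <- samples[seq_len(max_samples)]
  values <- rep(NA_real_, nrow(library))
  reasons <- rep(NA_character_, nrow(library))
  for (band_key in unique(paste(library$band_low, library$band_high))) {
    rows <- which(paste(library$band_low, library$band_high) == band_key)
    spec0 <- library[rows[1], ]
    filtered <- tryCatch(
      portrait_filter(samples, spec0$band_low, spec0$band_high, rate),
      lungchaos_error = function(e) e
    )
    if (inherits(filtered, "error")) {
      reasons[rows] <- conditionMessage(filtered)
      next
    }
    for (i in rows) {
      spec <- as.list(library[i, ])
      v <- tryCatch({
        pts <- portrait_points(filtered, spec)
        pts <- pts[is.finite(pts[, 1]) & is.finite(pts[, 2]), , drop = FALSE]
        if (nrow(pts) < 100L) {
          stop_lungchaos("fewer than 100 finite points", "lungchaos_length_error")
        }
        as.numeric(points_occupancy_entropy(pts, binning))
      }, lungchaos_error = function(e) e)
      if (inherits(v, "error")) reasons[i] <- conditionMessage(v) else values[i] <- v
    }
  }
  n_missing <- sum(is.na(values))
  if (n_missing > 0.1 * length(values)) {
    stop_lungchaos(
      sprintf("featurization failed for %d of %d portraits (first reason: %s)",
              n_missing, length(values), reasons[which(!is.na(reasons))[1]]),
      "lungchaos_featurize_error"
    )
  }
  values
}

#' Occupancy-entropy feature vector for one recording
#'
#' Conditions the recording and evaluates every portrait in the library on it
#' (band filters are computed once per band and shared). Per-portrait failures
#' are tolerated up to 10% of the library and reported as `NA`.
#'
#' @param recording A [new_recording()] object.
#' @param library A [build_library()] tibble.
#' @param binning A [binning_config()].
#' @param opts A [preprocess_options()].
#' @param max_samples Number of leading conditioned samples the portraits are
#'   computed on (caps per-recording cost; about 3.7 s at the default rate).
#' @return Numeric vector of entropies (bits), ordered by `portrait_id`.
#' @export
featurize <- function(recording, library = build_library(),
                      binning = binning_config(),
                      opts = preprocess_options(),
                      max_samples = 16384L) {
  conditioned <- preprocess(recording, opts)
  featurize_samples(conditioned$samples, conditioned$sample_rate,
                    library, binning, max_samples)
}

#' Feature matrix for all recordings of one site
#'
#' @param recordings Recordings tibble (see [generate_dataset()]); all rows
#'   must share one `site`.
#' @inheritParams featurize
#' @return A tibble: `subject_id`, `site`, then one `p<id>` column per
#'   portrait (entropy in bits).
#' @export
featurize_site <- function(recordings, library = build_library(),
                           binning = binning_config(),
                           opts = preprocess_options(),
                           max_samples = 16384L) {
  stopifnot(length(unique(recordings$site)) == 1L)
  feats <- purrr::pmap(recordings, function(subject_id, site, recording, ...) {
    featurize(recording, library, binning, opts, max_samples)
  })
  mat <- do.call(rbind, feats)
  colnames(mat) <- sprintf("p%03d", library$portrait_id)
  dplyr::bind_cols(
    tibble::tibble(subject_id = recordings$subject_id, site = recordings$site),
    tibble::as_tibble(mat)
  )
}

#' Entropy of one feature column
#'
#' Standardizes the values, bins them on [-3, 3] with `column_bins` equal-width
#' bins (outliers in the edge bins), and returns the Shannon entropy in bits.
#' Constant columns return `Inf` so the collapse skips them.
#'
#' @param values Numeric vector across recordings (>= 8 values).
#' @param binning A [binning_config()].
#' @return Entropy in bits, or `Inf` for a degenerate column.
#' @export
column_entropy <- function(values, binning = binning_config()) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) {
    stop_lungchaos("need at least 8 finite values", "lungchaos_insufficient_data_error")
  }
  s <- sd(values)
  if (s == 0) return(Inf)
  z <- (values - mean(values)) / s
  breaks <- seq(-3, 3, length.out = binning$column_bins + 1L)
  ib <- pmin(pmax(findInterval(z, breaks, all.inside = TRUE), 1L),
             binning$column_bins)
  shannon_bits(tabulate(ib, nbins = binning$column_bins) / length(z))
}

#' Collapse a feature matrix to two dimensions
#'
#' Unsupervised minimum-entropy selection: picks the pair of portrait columns
#' minimizing the sum of their [column_entropy()] values. The search is
#' exhaustive over all pairs up to 400 columns and greedy (best column, then
#' best partner) beyond; ties break toward the lexicographically smallest
#' portrait-id pair. Labels are never consulted, so the retained dimensions
#' are named portraits chosen purely for their clustered structure.
#'
#' @param features A [featurize_site()] tibble.
#' @param binning A [binning_config()].
#' @return An object of class `lungchaos_collapse`: `selected_portraits`
#'   (two column names), `coordinates` (tibble `subject_id`, `d1`, `d2`),
#'   `column_entropies` (tibble), `search_method`, `objective`.
#' @export
collapse <- function(features, binning = binning_config()) {
  cols <- setdiff(names(features), c("subject_id", "site"))
  ents <- vapply(cols, function(cn) column_entropy(features[[cn]], binning),
                 numeric(1))
  ok <- which(is.finite(ents))
  if (length(ok) < 2L) {
    stop_lungchaos("fewer than 2 non-degenerate feature columns",
                   "lungchaos_collapse_infeasible_error")
  }
  if (length(cols) <= 400L) {
    method <- "exhaustive"
    best <- NULL
    for (ai in seq_along(ok)) {
      for (bi in seq_along(ok)) {
        if (bi <= ai) next
        i <- ok[ai]; j <- ok[bi]
        obj <- ents[i] + ents[j]
        if (is.null(best) || obj < best$obj - 1e-12) best <- list(i = i, j = j, obj = obj)
      }
    }
  } else {
    method <- "greedy"
    i <- ok[which.min(ents[ok])]
    rest <- setdiff(ok, i)
    j <- rest[which.min(ents[rest])]
    best <- list(i = min(i, j), j = max(i, j), obj = ents[i] + ents[j])
  }
  sel <- cols[c(best$i, best$j)]
  structure(
    list(
      selected_portraits = sel,
      coordinates = tibble::tibble(
        subject_id = features$subject_id,
        d1 = features[[sel[1]]],
        d2 = features[[sel[2]]]
      ),
      column_entropies = tibble::tibble(portrait = cols, entropy = unname(ents)),
      search_method = method,
      objective = unname(best$obj),
      site = if ("site" %in% names(features)) features$site[1] else NA_character_
    ),
    class = "lungchaos_collapse"
  )
}

#' @export
print.lungchaos_collapse <- function(x, ...) {
  cat(sprintf("<lungchaos_collapse> site=%s  selected %s + %s (objective %.3f bits, %s)\n",
              x$site, x$selected_portraits[1], x$selected_portraits[2],
              x$objective, x$search_method))
  invisible(x)
}

#' Plot the collapsed 2-D coordinates
#'
#' @param object A [collapse()] result.
#' @param labels Optional tibble `subject_id`, `group` to color points.
#' @param ... Ignored.
#' @export
autoplot.lungchaos_collapse <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (!is.null(labels)) df <- dplyr::left_join(df, labels, by = "subject_id")
  aes <- if (!is.null(labels)) {
    ggplot2::aes(x = .data$d1, y = .data$d2, color = .data$group)
  } else {
    ggplot2::aes(x = .data$d1, y = .data$d2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s entropy (bits)", object$selected_portraits[1]),
      y = sprintf("%s entropy (bits)", object$selected_portraits[2])
    ) +
    ggplot2::theme_minimal()
}
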