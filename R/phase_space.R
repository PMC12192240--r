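# Delay embedding and phase-space portrait primitives.

#' Delay-embedding configuration
#'
#' @param delay Lag in samples between embedding coordinates.
#' @param dimension Embedding dimension m.
#' @param stride Subsampling stride over embedded points (used by the chaos
#'   estimators, not by the embedding itself).
#' @return A list of class `lungchaos_embedding`.
#' @export
embedding_config <- function(delay = 1L, dimension = 2L, stride = 1L) {
  if (delay < 1L || dimension < 1L || stride < 1L) {
    stop_lungchaos("delay, dimension and stride must all be >= 1",
                   "lungchaos_config_error")
  }
  structure(list(delay = as.integer(delay), dimension = as.integer(dimension),
                 stride = as.integer(stride)),
            class = "lungchaos_embedding")
}

#' Takens delay embedding
#'
#' Maps a scalar series to m-dimensional delay vectors
#' `(s[i], s[i + tau], ..., s[i + (m-1) tau])`.
#'
#' @param samples Numeric vector.
#' @param config An [embedding_config()].
#' @return A matrix with `length(samples) - (m - 1) * tau` rows and m columns.
#' @export
#' @examples
#' delay_embed(1:4, embedding_config(delay = 1, dimension = 2))
delay_embed <- function(samples, config) {
  tau <- config$delay
  m <- config$dimension
  n_out <- length(samples) - (m - 1L) * tau
  if (n_out < 1L) {
    stop_lungchaos("signal too short for the requested embedding",
                   "lungchaos_length_error")
  }
  out <- matrix(0, nrow = n_out, ncol = m)
  for (j in seq_len(m)) {
    out[, j] <- samples[seq.int((j - 1L) * tau + 1L, length.out = n_out)]
  }
  out
}

# Centered moving average with window w (odd); edges use the available window.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  # fill the w/2 edge NAs with shrinking-window means
  h <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(h)) {
    y[i] <- mean(x[1:(i + h)])
    y[n - i + 1L] <- mean(x[(n - i + 1L - h):n])
  }
  as.numeric(y)
}

#' Value-versus-slope phase portrait
#'
#' Plots each (smoothed) sample against its instantaneous slope, the classic
#' two-dimensional phase-space view of an auscultation trace. The slope is the
#' centered finite difference of a moving-average-smoothed copy of the signal
#' (window `smoothing` samples), in amplitude per sample.
#'
#' @param samples Numeric vector.
#' @param smoothing Moving-average window in samples (odd; 1 disables
#'   smoothing).
#' @return A two-column matrix (`x` = smoothed value, `y` = slope).
#' @export
derivative_portrait <- function(samples, smoothing = 5L) {
  smoothing <- as.integer(smoothing)
  if (length(samples) <= 2L * smoothing + 2L) {
    stop_lungchaos("signal too short for a derivative portrait",
                   "lungchaos_length_error")
  }
  s <- moving_average(samples, smoothing)
  n <- length(s)
  # keep only points whose smoothing window fits entirely inside the signal
  h <- (smoothing - 1L) %/% 2L
  idx <- (h + 2L):(n - h - 1L)
  cbind(x = s[idx], y = (s[idx + 1L] - s[idx - 1L]) / 2)
}

# Binned mutual information between x[t] and x[t + lag], in nats.
lagged_mutual_information <- function(x, lag, bins = 16L) {
  n <- length(x) - lag
  a <- x[1:n]
  b <- x[(lag + 1):(lag + n)]
  br <- seq(min(x), max(x), length.out = bins + 1L)
  ia <- pmin(pmax(findInterval(a, br, all.inside = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, br, all.inside = TRUE), 1L), bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / n
  px <- tabulate(ia, nbins = bins) / n
  py <- tabulate(ib, nbins = bins) / n
  pos <- joint > 0
  outer_p <- as.vector(outer(px, py))
  sum(joint[pos] * log(joint[pos] / outer_p[pos]))
}

#' Choose an embedding delay from the data
#'
#' Returns the first local minimum of the binned average mutual information
#' over lags `1..max_lag`. The raw histogram-MI curve is jagged, so the
#' minimum is taken on a 3-point smoothed curve, and it only counts if the
#' drop from the lag-1 value is both relative (below 80%) and well above the
#' histogram-MI estimation bias — flat noise-floor curves never qualify. If
#' no such minimum exists, falls back to the first lag at which the
#' autocorrelation drops below 1/e, and finally to lag 1.
#'
#' @param samples Numeric vector.
#' @param max_lag Largest lag examined, in samples.
#' @param bins Histogram bins per axis for the MI estimate.
#' @return Integer delay in samples.
#' @export
select_delay <- function(samples, max_lag = 50L, bins = 16L) {
  if (sd(samples) == 0) {
    stop_lungchaos("constant signal: no informative delay exists",
                   "lungchaos_degenerate_error")
  }
  max_lag <- min(max_lag, length(samples) - 2L)
  mi <- vapply(seq_len(max_lag), function(l) {
    lagged_mutual_information(samples, l, bins)
  }, numeric(1))
  k <- first_mi_minimum(mi, n_eff = length(samples) - max_lag, bins = bins)
  if (!is.na(k)) return(k)
  ac <- acf(samples, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  below <- which(ac < exp(-1))
  if (length(below)) below[1] else 1L
}

# First qualifying local minimum of a (raw) MI-vs-lag curve; NA if none.
first_mi_minimum <- function(mi, n_eff, bins) {
  max_lag <- length(mi)
  if (max_lag < 3L) return(NA_integer_)
  sm <- moving_average(mi, 3L)
  # bias of a bins x bins histogram MI estimate, nats; demand a drop well
  # above it so estimator jitter cannot fake a minimum
  bias <- (bins - 1)^2 / (2 * n_eff)
  for (k in 2:(max_lag - 1L)) {
    if (sm[k] <= sm[k - 1L] && sm[k] <= sm[k + 1L] &&
        sm[k] <= 0.8 * sm[1L] && (sm[1L] - sm[k]) >= 5 * bias) {
      return(k)
    }
  }
  NA_integer_
}

#' Close returns in an embedded trajectory
#'
#' Finds all pairs `(i, p)` for which the trajectory returns within `eps` of
#' itself after `p` steps (`min_period <= p <= max_period`) - the standard
#' diagnostic for unstable periodic orbits embedded in a chaotic attractor.
#'
#' @param points Embedded trajectory: a matrix of m-dimensional rows (a plain
#'   vector is treated as one-dimensional).
#' @param eps Return radius.
#' @param min_period,max_period Period search range in samples.
#' @return A tibble with `index`, `period`, `return_distance`, sorted by
#'   distance.
#' @export
close_returns <- function(points, eps, min_period, max_period) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (nrow(points) == 0L) {
    stop_lungchaos("empty point set", "lungchaos_input_error")
  }
  if (eps <= 0 || min_period >= max_period || max_period >= nrow(points)) {
    stop_lungchaos("require eps > 0 and min_period < max_period < n",
                   "lungchaos_config_error")
  }
  out <- close_returns_cpp(points, eps, as.integer(min_period),
                           as.integer(max_period))
  out <- tibble::as_tibble(out)
  dplyr::arrange(out, .data$return_distance)
}
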