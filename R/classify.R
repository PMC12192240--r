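# Case-clustered splits and ridge-regularized logistic classifiers.

#' Case-clustered 80/20 train/test split
#'
#' Seeded shuffle of the case ids; the first `round(fraction * n)` cases
#' (half away from zero) go to training, the rest to test. Recordings always
#' inherit their case's side, so no case ever straddles the split.
#'
#' @param case_ids Character vector of case (subject) identifiers.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer split seed.
#' @return A tibble `case_id`, `side` (`"train"`/`"test"`), with attributes
#'   `fraction` and `seed`.
#' @export
split_cases <- function(case_ids, fraction = 0.8, seed = 1550L) {
  if (length(case_ids) < 2L || anyDuplicated(case_ids)) {
    stop_lungchaos("need >= 2 distinct case ids", "lungchaos_split_error")
  }
  assert_number(fraction, "fraction", lower = 1e-9, upper = 1 - 1e-9)
  n_train <- round_half_up(fraction * length(case_ids))
  if (n_train < 1L || n_train >= length(case_ids)) {
    stop_lungchaos("split leaves train or test side empty", "lungchaos_split_error")
  }
  shuffled <- withr::with_seed(seed, sample(case_ids))
  out <- tibble::tibble(
    case_id = shuffled,
    side = c(rep("train", n_train), rep("test", length(case_ids) - n_train))
  )
  out <- out[order(match(out$case_id, case_ids)), ]
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Ridge-regularized logistic regression via IRLS
#'
#' Standardizes the feature columns, then maximizes the ridge-penalized
#' binomial log-likelihood (penalty on slopes only, not the intercept) by
#' iteratively reweighted least squares with step halving. The small default
#' ridge keeps coefficients finite on separable data while leaving
#' well-conditioned fits essentially unpenalized.
#'
#' @param features Numeric matrix (n x k) or data frame of predictors.
#' @param labels Binary vector (logical, 0/1, or a 2-level factor where the
#'   second level is the positive class).
#' @param ridge Penalty weight on standardized slopes.
#' @param max_iter,tol IRLS iteration cap and max-coefficient-change tolerance.
#' @return An object of class `lungchaos_logistic`.
#' @export
fit_logistic <- function(features, labels, ridge = 1e-6,
                         max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as_binary_labels(labels)
  if (nrow(X) != length(y)) {
    stop_lungchaos("features and labels disagree in length", "lungchaos_shape_error")
  }
  if (length(unique(y)) < 2L) {
    stop_lungchaos("labels contain a single class", "lungchaos_degenerate_labels_error")
  }
  if (nrow(X) <= ncol(X)) {
    stop_lungchaos("need more observations than features", "lungchaos_shape_error")
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) {
    stop_lungchaos("constant feature column", "lungchaos_degenerate_error")
  }
  Z <- cbind(1, sweep(sweep(X, 2, mu), 2, sds, "/"))
  k <- ncol(Z)
  pen <- diag(c(0, rep(ridge, k - 1L)))
  beta <- numeric(k)
  loglik <- function(b) {
    eta <- drop(Z %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * ridge * sum(b[-1]^2)
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(Z, y - p)) - ridge * c(0, beta[-1])
    H <- crossprod(Z, Z * w) + pen
    step <- solve(H, grad)
    new_beta <- beta + step
    # step halving keeps the penalized likelihood monotone on hard problems
    new_ll <- loglik(new_beta)
    halvings <- 0L
    while (!is.finite(new_ll) || (new_ll < ll - 1e-10 && halvings < 20L)) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    ll <- new_ll
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(
    list(intercept = beta[1], coefficients = beta[-1],
         feature_means = mu, feature_sds = sds,
         feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
         ridge = ridge, converged = converged, n_iter = iter,
         loglik = ll, n = nrow(X)),
    class = "lungchaos_logistic"
  )
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else if (is.logical(labels)) as.integer(labels)
  else if (is.character(labels)) as.integer(labels == "COPD")
  else as.integer(labels != 0)
}

#' Predicted class probabilities
#'
#' Logistic transform of the standardized linear predictor; values lie
#' strictly in (0, 1).
#'
#' @param object A [fit_logistic()] model.
#' @param features Matrix or data frame with the model's feature width.
#' @param ... Ignored.
#' @return Numeric probability vector.
#' @export
predict.lungchaos_logistic <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != length(object$coefficients)) {
    stop_lungchaos("feature width does not match the model", "lungchaos_shape_error")
  }
  Z <- sweep(sweep(X, 2, object$feature_means), 2, object$feature_sds, "/")
  eta <- object$intercept + drop(Z %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' @export
print.lungchaos_logistic <- function(x, ...) {
  cat(sprintf("<lungchaos_logistic> %d features, n=%d, ridge=%g, %s in %d iter\n",
              length(x$coefficients), x$n, x$ridge,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `lungchaos_logistic` model.
#' @param ... Ignored.
#' @export
tidy.lungchaos_logistic <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(x$intercept, x$coefficients)
  )
}

#' @rdname fit_logistic
#' @export
glance.lungchaos_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n, ridge = x$ridge, converged = x$converged,
    n_iter = x$n_iter, log_likelihood = x$loglik
  )
}

# Average repeated recordings down to one coordinate pair per case and return
# the per-case design matrix aligned to `cases`.
case_coordinates <- function(coords, cases) {
  agg <- coords |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("d"), mean), .groups = "drop")
  missing <- setdiff(cases, agg$subject_id)
  if (length(missing)) {
    stop_lungchaos(
      sprintf("no coordinates for case(s): %s", paste(missing, collapse = ", ")),
      "lungchaos_coverage_error"
    )
  }
  agg[match(cases, agg$subject_id), ]
}

#' Fit the per-site logistic model
#'
#' Fits the 2-D collapsed coordinates of one site to the COPD label on the
#' training cases only. Multiple recordings per case are averaged in
#' coordinate space first, so the model sees one observation per case and the
#' test side is never touched.
#'
#' @param coords A [collapse()] result (or its `coordinates` tibble).
#' @param labels Tibble `subject_id`, `group`.
#' @param split A [split_cases()] assignment.
#' @param ridge Ridge penalty passed to [fit_logistic()].
#' @return A `lungchaos_logistic` model.
#' @export
fit_site_model <- function(coords, labels, split, ridge = 1e-6) {
  if (inherits(coords, "lungchaos_collapse")) coords <- coords$coordinates
  train_cases <- split$case_id[split$side == "train"]
  cc <- case_coordinates(coords, train_cases)
  y <- labels$group[match(train_cases, labels$subject_id)]
  X <- as.matrix(cc[, c("d1", "d2")])
  fit_logistic(X, y, ridge = ridge)
}

#' Fit the composite model
#'
#' Concatenates the egophony and axillary 2-D coordinates into one 4-D
#' per-case feature vector and fits a single logistic model on the training
#' cases: one model over both auscultation sources rather than a fusion of
#' per-site probabilities.
#'
#' @param ego_coords,ax_coords Per-site [collapse()] results (or coordinate
#'   tibbles).
#' @inheritParams fit_site_model
#' @return A `lungchaos_logistic` model over features
#'   `ego_d1, ego_d2, ax_d1, ax_d2`.
#' @export
fit_composite <- function(ego_coords, ax_coords, labels, split, ridge = 1e-6) {
  X <- composite_features(ego_coords, ax_coords,
                          split$case_id[split$side == "train"])
  y <- labels$group[match(split$case_id[split$side == "train"], labels$subject_id)]
  fit_logistic(X, y, ridge = ridge)
}

# 4-D composite design matrix for the given cases.
composite_features <- function(ego_coords, ax_coords, cases) {
  if (inherits(ego_coords, "lungchaos_collapse")) ego_coords <- ego_coords$coordinates
  if (inherits(ax_coords, "lungchaos_collapse")) ax_coords <- ax_coords$coordinates
  e <- case_coordinates(ego_coords, cases)
  a <- case_coordinates(ax_coords, cases)
  X <- cbind(ego_d1 = e$d1, ego_d2 = e$d2, ax_d1 = a$d1, ax_d2 = a$d2)
  rownames(X) <- cases
  X
}
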