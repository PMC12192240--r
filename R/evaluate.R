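# Confusion-matrix evaluation, subgroup accuracy, and group comparisons.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(concordant pairs + 0.5 x tied pairs) / (n_pos x n_neg)`, computed via
#' midranks; exact for any input, equal to trapezoidal ROC integration.
#'
#' @param probs Numeric score/probability vector.
#' @param labels Binary labels (see [fit_logistic()] for accepted encodings).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(probs, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_lungchaos("AUC undefined with a single class", "lungchaos_degenerate_labels_error")
  }
  r <- rank(probs)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating threshold
#'
#' Scans the observed probabilities as candidate cuts (predicted positive when
#' `prob >= threshold`) and returns the lowest threshold maximizing Youden's
#' J = sensitivity + specificity - 1.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
youden_threshold <- function(probs, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop_lungchaos("threshold undefined with a single class",
                   "lungchaos_degenerate_labels_error")
  }
  cand <- sort(unique(probs))
  j <- vapply(cand, function(t) {
    cm <- confusion_at(probs, y, t)
    cm[["sensitivity"]] + cm[["specificity"]] - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Predicted positive iff `prob >= threshold`. Degenerate sides (no positives
#' or no negatives) yield `NA` for the affected rate rather than 0/0.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_at <- function(probs, labels, threshold) {
  y <- as_binary_labels(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  c(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(y)
  )
}

#' Evaluate the per-site and composite models on both split sides
#'
#' Produces the six confusion reports (egophony, axillary, composite x
#' train, test). The operating threshold of each model is chosen by Youden's J
#' on the train side only and reused unchanged on the test side, so test data
#' never influence the operating point.
#'
#' @param models Named list with elements `egophony`, `axillary`, `composite`
#'   ([fit_logistic()] objects).
#' @param coords Named list with per-site [collapse()] results (`egophony`,
#'   `axillary`).
#' @param labels Tibble `subject_id`, `group`.
#' @param split A [split_cases()] assignment.
#' @return A tibble with columns `model`, `side`, `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, `n`, plus a `probabilities`
#'   attribute (per-case tibble) for downstream subgroup analysis.
#' @export
evaluate_models <- function(models, coords, labels, split) {
  feature_for <- function(model_name, cases) {
    switch(model_name,
      egophony = as.matrix(case_coordinates(coords$egophony$coordinates, cases)[, c("d1", "d2")]),
      axillary = as.matrix(case_coordinates(coords$axillary$coordinates, cases)[, c("d1", "d2")]),
      composite = composite_features(coords$egophony, coords$axillary, cases)
    )
  }
  sides <- list(train = split$case_id[split$side == "train"],
                test = split$case_id[split$side == "test"])
  probs_rows <- list()
  rows <- list()
  for (mn in c("egophony", "axillary", "composite")) {
    tr_cases <- sides$train
    p_train <- predict(models[[mn]], feature_for(mn, tr_cases))
    y_train <- labels$group[match(tr_cases, labels$subject_id)]
    thr <- youden_threshold(p_train, y_train)
    for (sd_ in c("train", "test")) {
      cases <- sides[[sd_]]
      p <- predict(models[[mn]], feature_for(mn, cases))
      y <- labels$group[match(cases, labels$subject_id)]
      cm <- confusion_at(p, y, thr)
      # a degenerate (single-class) side reports a missing AUC, not an error
      auc <- tryCatch(roc_auc(p, y),
                      lungchaos_degenerate_labels_error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mn, side = sd_, auc = auc,
        sensitivity = cm[["sensitivity"]], specificity = cm[["specificity"]],
        accuracy = cm[["accuracy"]], threshold = thr, n = length(cases)
      )
      probs_rows[[length(probs_rows) + 1L]] <- tibble::tibble(
        model = mn, side = sd_, case_id = cases, prob = p,
        label = as_binary_labels(y), threshold = thr
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "probabilities") <- dplyr::bind_rows(probs_rows)
  class(out) <- c("lungchaos_reports", class(out))
  out
}

#' Standard subgroup definitions
#'
#' Returns the long table of subgroup memberships mirroring the published
#' subgroup analysis: BMI above/at-or-below 30, age bands (<50, 50-64, >=65),
#' sex, White/not White, each comorbidity flag (history / no history), and
#' tobacco ever/never.
#'
#' @param subjects A [generate_cohort()] tibble.
#' @return A tibble `subgroup`, `subject_id`.
#' @export
default_subgroups <- function(subjects) {
  defs <- list(
    "BMI > 30" = subjects$bmi > 30,
    "BMI <= 30" = subjects$bmi <= 30,
    "Age < 50" = subjects$age < 50,
    "Age 50-64" = subjects$age >= 50 & subjects$age < 65,
    "Age >= 65" = subjects$age >= 65,
    "Male" = subjects$sex == "male",
    "Female" = subjects$sex == "female",
    "White" = subjects$race == "White",
    "Not White" = subjects$race != "White"
  )
  for (fl in comorbidity_flags) {
    label <- if (fl == "tobacco_ever") "Tobacco ever" else paste("Hx", fl)
    nolabel <- if (fl == "tobacco_ever") "Tobacco never" else paste("Hx no", fl)
    defs[[label]] <- subjects[[fl]]
    defs[[nolabel]] <- !subjects[[fl]]
  }
  purrr::imap_dfr(defs, function(mask, name) {
    tibble::tibble(subgroup = name, subject_id = subjects$subject_id[mask])
  })
}

#' Classification accuracy across patient subgroups
#'
#' Accuracy of a model's thresholded predictions within each subgroup,
#' separately for the train and test sides. Subgroups with an empty test side
#' report `NA` rather than zero.
#'
#' @param predictions Per-case predictions for one model: tibble `case_id`,
#'   `side`, `prob`, `label`, `threshold` (one model's slice of the
#'   `probabilities` attribute of [evaluate_models()]).
#' @param subjects A [generate_cohort()] tibble.
#' @param subgroups Subgroup membership tibble; defaults to
#'   [default_subgroups()].
#' @return A tibble `subgroup`, `n`, `n_train`, `n_test`, `train_accuracy`,
#'   `test_accuracy`.
#' @export
subgroup_accuracy <- function(predictions, subjects, subgroups = NULL) {
  subgroups <- subgroups %||% default_subgroups(subjects)
  if (!all(subgroups$subject_id %in% predictions$case_id)) {
    missing <- setdiff(subgroups$subject_id, predictions$case_id)
    stop_lungchaos(
      sprintf("subgroup members lack predictions: %s",
              paste(head(missing, 5), collapse = ", ")),
      "lungchaos_definition_error"
    )
  }
  preds <- dplyr::mutate(predictions,
                         correct = (.data$prob >= .data$threshold) == (.data$label == 1L))
  joined <- dplyr::inner_join(subgroups, preds,
                              by = c(subject_id = "case_id"),
                              relationship = "many-to-many")
  joined |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_train = sum(.data$side == "train"),
      n_test = sum(.data$side == "test"),
      train_accuracy = if (any(.data$side == "train"))
        mean(.data$correct[.data$side == "train"]) else NA_real_,
      test_accuracy = if (any(.data$side == "test"))
        mean(.data$correct[.data$side == "test"]) else NA_real_,
      .groups = "drop"
    )
}

#' Between-group comparison statistics for the cohort table
#'
#' Continuous variables are compared with the Mann-Whitney rank-sum test
#' (exact enumeration when both groups have at most 10 untied observations,
#' the tie-corrected normal approximation otherwise); binary variables with
#' the chi-squared test, switching to Fisher's exact test for 2x2 tables with
#' any expected cell below 5. Degenerate variables report a missing p-value.
#' No multiplicity correction is applied; p-values are reported raw.
#'
#' @param subjects A [generate_cohort()] tibble.
#' @return A tibble `variable`, `type`, `copd_summary`, `control_summary`,
#'   `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(subjects) {
  g <- subjects$group == "COPD"
  if (!any(g) || all(g)) {
    stop_lungchaos("both groups must be nonempty", "lungchaos_degenerate_labels_error")
  }
  cont_vars <- c("age", "bmi", "fvc", "fev1", "fev1_fvc", "cat_total")
  cat_vars <- c(sex = "female", race = "White", stats::setNames(comorbidity_flags, comorbidity_flags))

  summarise_med <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  rows <- purrr::map(cont_vars, function(v) {
    x <- subjects[[v]][g]; y <- subjects[[v]][!g]
    res <- mann_whitney(x, y)
    tibble::tibble(variable = v, type = "continuous",
                   copd_summary = summarise_med(x), control_summary = summarise_med(y),
                   test = res$test, statistic = res$statistic, p_value = res$p)
  })
  cat_rows <- purrr::imap(cat_vars, function(level, v) {
    val <- if (v %in% c("sex", "race")) subjects[[v]] == level else subjects[[v]]
    tab <- table(factor(val, levels = c(FALSE, TRUE)), factor(g, levels = c(FALSE, TRUE)))
    summ <- function(keep) sprintf("%d (%.1f%%)", sum(val & keep), 100 * mean(val[keep]))
    if (length(unique(val)) < 2L) {
      return(tibble::tibble(variable = v, type = "categorical",
                            copd_summary = summ(g), control_summary = summ(!g),
                            test = "none", statistic = NA_real_, p_value = NA_real_))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      tibble::tibble(variable = v, type = "categorical",
                     copd_summary = summ(g), control_summary = summ(!g),
                     test = "fisher_exact", statistic = unname(ft$estimate),
                     p_value = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      tibble::tibble(variable = v, type = "categorical",
                     copd_summary = summ(g), control_summary = summ(!g),
                     test = "chi_squared", statistic = unname(ct$statistic),
                     p_value = ct$p.value)
    }
  })
  dplyr::bind_rows(c(rows, unname(cat_rows)))
}

# Mann-Whitney rank-sum: exact enumeration for small untied samples,
# tie-corrected normal approximation otherwise.
mann_whitney <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && length(x) <= 10 && length(y) <= 10) {
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    list(test = "mann_whitney_exact", statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    list(test = "mann_whitney", statistic = unname(wt$statistic), p = wt$p.value)
  }
}
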