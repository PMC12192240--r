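# ROC/AUC, operating thresholds, confusion metrics, subgroup accuracy and
# group-comparison statistics.

# Trapezoidal ROC integration, written independently of the rank formulation.
auc_trapezoid <- function(probs, labels) {
  y <- as.integer(labels != 0)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(probs[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(probs[y == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

test_that("AUC pair counting evaluates the textbook examples exactly", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)),
               class = "lungchaos_degenerate_labels_error")
})

test_that("rank AUC equals trapezoidal integration on 200 random instances", {
  withr::with_seed(60, {
    for (i in 1:200) {
      n <- sample(6:40, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      p <- round(runif(n), sample(c(1, 2, 7), 1))  # ties included
      expect_equal(roc_auc(p, y), auc_trapezoid(p, y), tolerance = 1e-12)
    }
  })
})

test_that("rank AUC agrees with the pROC reference implementation", {
  withr::with_seed(61, {
    y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
    p <- runif(60)
  })
  expect_equal(roc_auc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Youden threshold matches an exhaustive scan and its edge cases", {
  withr::with_seed(62, {
    for (i in 1:25) {
      n <- sample(8:30, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      p <- round(runif(n), 2)
      thr <- youden_threshold(p, y)
      cand <- sort(unique(p))
      j <- vapply(cand, function(t) {
        sum(p >= t & y == 1) / sum(y == 1) + sum(p < t & y == 0) / sum(y == 0) - 1
      }, numeric(1))
      expect_equal(thr, cand[which.max(j)])
    }
  })
  # perfectly separated: lowest candidate above all negatives
  expect_equal(youden_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1)), 0.7)
  # fully tied probabilities: single candidate with J = 0
  expect_equal(youden_threshold(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.4)
})

test_that("confusion metrics count the matrix correctly", {
  p <- c(0.9, 0.4, 0.6, 0.2); y <- c(1, 1, 0, 0)
  cm <- confusion_at(p, y, 0.5)
  expect_equal(unname(cm), c(0.5, 0.5, 0.5))
  expect_equal(unname(confusion_at(p, y, 0)), c(1, 0, 0.5))
  expect_equal(unname(confusion_at(p, y, 0.95)), c(0, 1, 0.5))
  degen <- confusion_at(c(0.2, 0.8), c(1, 1), 0.5)
  expect_true(is.na(degen[["specificity"]]))
})

make_eval_setup <- function(sep = 2.5, seed = 63) {
  subjects <- generate_cohort(cohort_config(seed = seed))
  labels <- subjects[, c("subject_id", "group")]
  mk <- function(s) {
    structure(list(
      coordinates = withr::with_seed(s, tibble::tibble(
        subject_id = subjects$subject_id,
        d1 = rnorm(108) + sep * (subjects$group == "COPD"),
        d2 = rnorm(108)
      ))), class = "lungchaos_collapse")
  }
  coords <- list(egophony = mk(seed + 1), axillary = mk(seed + 2))
  split <- split_cases(subjects$subject_id, 0.8, seed = seed + 3)
  models <- list(
    egophony = fit_site_model(coords$egophony, labels, split),
    axillary = fit_site_model(coords$axillary, labels, split),
    composite = fit_composite(coords$egophony, coords$axillary, labels, split)
  )
  list(subjects = subjects, labels = labels, coords = coords,
       split = split, models = models)
}

test_that("evaluate_models produces the six train/test reports", {
  s <- make_eval_setup()
  reports <- evaluate_models(s$models, s$coords, s$labels, s$split)
  expect_equal(nrow(reports), 6L)
  expect_setequal(unique(reports$model), c("egophony", "axillary", "composite"))
  expect_equal(reports$n[reports$side == "train"], rep(86L, 3))
  expect_equal(reports$n[reports$side == "test"], rep(22L, 3))
  expect_true(all(reports$auc >= 0 & reports$auc <= 1))
  # per model, the threshold is shared between train and test rows
  per_model <- dplyr::summarise(dplyr::group_by(reports, model),
                                k = dplyr::n_distinct(threshold))
  expect_true(all(per_model$k == 1L))
})

test_that("the operating threshold is a pure function of the train side", {
  s <- make_eval_setup(seed = 64)
  r1 <- evaluate_models(s$models, s$coords, s$labels, s$split)
  # flipping labels of test cases must not move any threshold
  labels2 <- s$labels
  test_ids <- s$split$case_id[s$split$side == "test"]
  flip <- match(test_ids, labels2$subject_id)
  labels2$group[flip] <- ifelse(labels2$group[flip] == "COPD", "control", "COPD")
  r2 <- evaluate_models(s$models, s$coords, labels2, s$split)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(r1$auc[r1$side == "train"], r2$auc[r2$side == "train"])
})

test_that("subgroup accuracies partition the cohort and honor empty sides", {
  s <- make_eval_setup(seed = 65)
  reports <- evaluate_models(s$models, s$coords, s$labels, s$split)
  preds <- attr(reports, "probabilities")
  comp <- preds[preds$model == "composite", ]
  sg <- subgroup_accuracy(comp, s$subjects)
  bmi <- sg[sg$subgroup %in% c("BMI > 30", "BMI <= 30"), ]
  expect_equal(sum(bmi$n), 108L)
  expect_equal(sum(bmi$n_train), 86L)
  age <- sg[grepl("^Age", sg$subgroup), ]
  expect_equal(sum(age$n), 108L)
  expect_true(all(sg$n == sg$n_train + sg$n_test))
  ok <- !is.na(sg$test_accuracy)
  expect_true(all(sg$test_accuracy[ok] >= 0 & sg$test_accuracy[ok] <= 1))

  # all-correct predictions give accuracy 1 everywhere
  perfect <- comp
  perfect$prob <- ifelse(perfect$label == 1L, 0.99, 0.01)
  perfect$threshold <- 0.5
  sg2 <- subgroup_accuracy(perfect, s$subjects)
  expect_true(all(sg2$train_accuracy[!is.na(sg2$train_accuracy)] == 1))
  expect_true(all(sg2$test_accuracy[!is.na(sg2$test_accuracy)] == 1))
})

test_that("exact rank-sum and Fisher tests reproduce enumeration results", {
  # {1,2} vs {3,4}: 2-sided exact Mann-Whitney p = 1/3
  mw <- lungchaos:::mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$test, "mann_whitney_exact")
  # [[3,1],[1,3]]: Fisher two-sided p = 34/70
  ft <- stats::fisher.test(matrix(c(3, 1, 1, 3), 2))
  expect_equal(ft$p.value, 34 / 70, tolerance = 1e-9)
  # [[10,10],[10,10]]: chi-squared statistic 0, p = 1
  ct <- stats::chisq.test(matrix(c(10, 10, 10, 10), 2), correct = FALSE)
  expect_equal(unname(ct$statistic), 0)
  expect_equal(ct$p.value, 1)
})

test_that("compare_groups dispatches tests by type and cell size", {
  subjects <- generate_cohort(cohort_config(seed = 66L))
  cmp <- compare_groups(subjects)
  expect_true(all(c("age", "bmi", "fev1_fvc", "cat_total", "sex", "asthma") %in%
                    cmp$variable))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
  expect_true(all(cmp$test[cmp$type == "continuous"] %in%
                    c("mann_whitney", "mann_whitney_exact")))
  # the engineered group difference in FEV1/FVC is overwhelming
  expect_lt(cmp$p_value[cmp$variable == "fev1_fvc"], 1e-10)
  # rarer flags with small expected cells go through Fisher
  expect_true(all(cmp$test[cmp$type == "categorical"] %in%
                    c("chi_squared", "fisher_exact", "none")))
})

test_that("chi-squared and Fisher p-values agree on large balanced tables", {
  tab <- matrix(c(300, 200, 250, 250), 2)
  p_chi <- stats::chisq.test(tab, correct = FALSE)$p.value
  p_fis <- stats::fisher.test(tab)$p.value
  expect_lt(abs(p_chi - p_fis), 0.02)
})
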