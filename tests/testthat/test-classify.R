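# Case-clustered splits and the ridge-IRLS logistic classifier.

test_that("80/20 split of 108 cases gives 86 train / 22 test, deterministically", {
  ids <- sprintf("S%03d", 1:108)
  sp <- split_cases(ids, 0.8, seed = 5L)
  expect_equal(sum(sp$side == "train"), 86L)
  expect_equal(sum(sp$side == "test"), 22L)
  expect_identical(sp, split_cases(ids, 0.8, seed = 5L))
  expect_false(identical(sp$side, split_cases(ids, 0.8, seed = 6L)$side))

  sp10 <- split_cases(sprintf("C%d", 1:10), 0.8, seed = 1L)
  expect_equal(sum(sp10$side == "train"), 8L)
  expect_equal(sum(sp10$side == "test"), 2L)

  expect_error(split_cases(c("a", "b"), 0.9, seed = 1L),
               class = "lungchaos_split_error")
  expect_error(split_cases(c("a", "a", "b"), 0.5, seed = 1L),
               class = "lungchaos_split_error")
})

test_that("recordings always inherit their case's split side", {
  ids <- sprintf("S%03d", 1:40)
  sp <- split_cases(ids, 0.8, seed = 2L)
  recordings <- tidyr::expand_grid(case_id = ids, site = c("egophony", "axillary"))
  joined <- dplyr::left_join(recordings, sp, by = "case_id")
  sides_per_case <- dplyr::summarise(dplyr::group_by(joined, case_id),
                                     k = dplyr::n_distinct(side))
  expect_true(all(sides_per_case$k == 1L))
})

test_that("point-symmetric data yields a near-zero intercept", {
  x <- withr::with_seed(40, matrix(rnorm(400), ncol = 2))
  X <- rbind(x, -x)
  y <- rep(c(1, 0), each = 200)
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$intercept), 1e-6)
})

test_that("simulated logistic data recovers the coefficients within 3 SE", {
  n <- 5000
  beta <- c(0.8, -0.5); intercept <- 0.3
  withr::with_seed(41, {
    X <- matrix(rnorm(2 * n), ncol = 2)
    p <- 1 / (1 + exp(-(intercept + X %*% beta)))
    y <- rbinom(n, 1, p)
  })
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  est <- c(fit$intercept - sum(fit$coefficients * fit$feature_means / fit$feature_sds),
           fit$coefficients / fit$feature_sds)  # back to the raw scale
  expect_lt(abs(est[2] - beta[1]), 3 * se[2])
  expect_lt(abs(est[3] - beta[2]), 3 * se[3])
  # and agrees with the IRLS reference fit at negligible ridge
  expect_equal(unname(est), unname(coef(ref)), tolerance = 1e-3)
})

test_that("separable data stays finite and converges under ridge", {
  X <- matrix(c(-2, -1, 1, 2, -2.5, -1.5, 1.5, 2.5), ncol = 1)
  y <- as.numeric(X > 0)
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  expect_equal(roc_auc(predict(fit, X), y), 1.0)
})

test_that("predictions reproduce the logistic formula", {
  model <- structure(
    list(intercept = 0.5, coefficients = c(1, -2),
         feature_means = c(0, 0), feature_sds = c(1, 1),
         feature_names = c("a", "b"), ridge = 0, converged = TRUE,
         n_iter = 0L, loglik = NA_real_, n = 0L),
    class = "lungchaos_logistic"
  )
  X <- rbind(c(0, 0), c(1, 0.5), c(-1, 2))
  expect_equal(predict(model, X), 1 / (1 + exp(-c(0.5, 0.5, -4.5))))
  # zero coefficients, zero intercept -> coin flip everywhere
  model$intercept <- 0; model$coefficients <- c(0, 0)
  expect_equal(predict(model, X), rep(0.5, 3))
  expect_error(predict(model, matrix(1, ncol = 3, nrow = 1)),
               class = "lungchaos_shape_error")
})

test_that("features at the training mean map to plogis(intercept)", {
  X <- withr::with_seed(42, matrix(rnorm(200), ncol = 2))
  y <- withr::with_seed(43, rbinom(100, 1, 0.5))
  fit <- fit_logistic(X, y)
  p0 <- predict(fit, matrix(colMeans(X), nrow = 1))
  expect_equal(p0, 1 / (1 + exp(-fit$intercept)), tolerance = 1e-12)
})

test_that("single-class labels are refused", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_logistic(X, rep(1, 10)),
               class = "lungchaos_degenerate_labels_error")
})

test_that("the ridge path is flat on well-conditioned fits", {
  withr::with_seed(44, {
    X <- matrix(rnorm(600), ncol = 2)
    y <- rbinom(300, 1, 1 / (1 + exp(-X[, 1])))
  })
  f1 <- fit_logistic(X, y, ridge = 1e-6)
  f2 <- fit_logistic(X, y, ridge = 1e-4)
  expect_lt(max(abs(f1$coefficients - f2$coefficients) / abs(f1$coefficients)), 0.01)
})

make_site_coords <- function(subjects, sep = 2, seed = 45) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = subjects$subject_id,
    d1 = rnorm(nrow(subjects)) + sep * (subjects$group == "COPD"),
    d2 = rnorm(nrow(subjects))
  ))
}

test_that("site models fit on train cases only, matching a manual subset fit", {
  subjects <- generate_cohort(cohort_config(n_copd = 20, n_control = 20, seed = 46L))
  labels <- subjects[, c("subject_id", "group")]
  coords <- make_site_coords(subjects)
  sp <- split_cases(subjects$subject_id, 0.8, seed = 47L)
  fit <- fit_site_model(coords, labels, sp)
  train_ids <- sp$case_id[sp$side == "train"]
  manual <- fit_logistic(
    as.matrix(coords[match(train_ids, coords$subject_id), c("d1", "d2")]),
    labels$group[match(train_ids, labels$subject_id)]
  )
  expect_equal(fit$coefficients, manual$coefficients)
  expect_equal(fit$intercept, manual$intercept)
})

test_that("a duplicated site composite matches the single-site model", {
  subjects <- generate_cohort(cohort_config(n_copd = 20, n_control = 20, seed = 48L))
  labels <- subjects[, c("subject_id", "group")]
  coords <- make_site_coords(subjects)
  sp <- split_cases(subjects$subject_id, 0.8, seed = 49L)
  site_fit <- fit_site_model(coords, labels, sp)
  comp_fit <- fit_composite(coords, coords, labels, sp)
  cases <- sp$case_id[sp$side == "train"]
  X2 <- as.matrix(coords[match(cases, coords$subject_id), c("d1", "d2")])
  auc_site <- roc_auc(predict(site_fit, X2),
                      labels$group[match(cases, labels$subject_id)])
  X4 <- cbind(X2, X2)
  auc_comp <- roc_auc(predict(comp_fit, X4),
                      labels$group[match(cases, labels$subject_id)])
  expect_equal(auc_comp, auc_site, tolerance = 1e-6)
})

test_that("permuted labels give chance-level training AUC", {
  subjects <- generate_cohort(cohort_config(seed = 50L))
  labels <- subjects[, c("subject_id", "group")]
  labels$group <- withr::with_seed(51, sample(labels$group))
  coords <- make_site_coords(subjects, sep = 0, seed = 52)
  sp <- split_cases(subjects$subject_id, 0.8, seed = 53L)
  fit <- fit_site_model(coords, labels, sp)
  cases <- sp$case_id[sp$side == "train"]
  X <- as.matrix(coords[match(cases, coords$subject_id), c("d1", "d2")])
  auc <- roc_auc(predict(fit, X), labels$group[match(cases, labels$subject_id)])
  expect_lt(abs(auc - 0.5), 0.15)
})
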