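# Synthetic cohort generation.
#
# The generator emulates a 108-subject two-arm auscultation study: 52 subjects
# with spirometry-confirmed COPD (FEV1/FVC < 70%) and 56 controls
# (FEV1/FVC > 70%), with group demographics, spirometry and COPD assessment
# test (CAT) responses matching the published summary tables.

#' Comorbidity flags carried by every synthetic subject
#' @keywords internal
comorbidity_flags <- c(
  "asthma", "ILD", "HTN", "CAD", "HLD", "DM2", "CKD_ESRD", "HF", "tobacco_ever"
)

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the published study's cohort structure: 52 COPD / 56
#' control subjects, group age and BMI summaries (median/IQR/range), sex and
#' race mix, comorbidity prevalences, group FEV1/FVC means and SDs, and a
#' shared CAT item distribution whose total score has median near 16.
#'
#' Ages and BMI are drawn from piecewise-linear quantile functions through the
#' configured (min, Q1, median, Q3, max). FEV1/FVC is drawn from a normal
#' truncated at the 70% diagnostic cut (below for COPD, above for controls)
#' whose location is calibrated so the truncated mean equals the configured
#' group mean exactly (see [calibrate_truncated_location()]).
#'
#' @param n_copd,n_control Group sizes.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @param age_quantiles_per_group,bmi_quantiles_per_group Named lists
#'   (`copd`, `control`) of 5-point quantile summaries.
#' @param female_fraction_per_group,race_probs_per_group Per-group sex and
#'   race composition.
#' @param fev1fvc_mean_sd_per_group Per-group target mean and SD of the
#'   FEV1/FVC ratio in percent.
#' @param fvc_mean_sd Group-shared FVC mean and SD in liters (the study found
#'   no significant FVC difference); draws are truncated below at
#'   `fvc_floor` liters.
#' @param fvc_floor Lower bound for FVC draws, liters.
#' @param comorbidity_prevalence Named vector of Bernoulli prevalences for the
#'   flags in `comorbidity_flags`.
#' @param cat_item_probs Shared probability vector over item scores 0-5 used
#'   for all 8 CAT items in both groups.
#' @return A list of class `lungchaos_cohort_config`.
#' @export
cohort_config <- function(n_copd = 52L,
                          n_control = 56L,
                          seed = 1550L,
                          age_quantiles_per_group = list(
                            copd = c(19, 56, 63, 70, 85),
                            control = c(19, 39, 57.5, 66.5, 85)
                          ),
                          female_fraction_per_group = c(copd = 0.654, control = 0.661),
                          race_probs_per_group = list(
                            copd = c(White = 0.596, Black = 0.404, Asian = 0),
                            control = c(White = 0.589, Black = 0.393, Asian = 0.018)
                          ),
                          bmi_quantiles_per_group = list(
                            copd = c(11.6, 23.5, 28.4, 31.2, 65.4),
                            control = c(11.6, 25.1, 31.2, 37.5, 65.4)
                          ),
                          fev1fvc_mean_sd_per_group = list(
                            copd = c(mean = 56.30, sd = 10.47),
                            control = c(mean = 79.52, sd = 9.75)
                          ),
                          fvc_mean_sd = c(mean = 2.80, sd = 0.90),
                          fvc_floor = 0.5,
                          comorbidity_prevalence = c(
                            asthma = 33 / 108, ILD = 19 / 108, HTN = 58 / 108,
                            CAD = 16 / 108, HLD = 49 / 108, DM2 = 25 / 108,
                            CKD_ESRD = 17 / 108, HF = 11 / 108,
                            tobacco_ever = 80 / 108
                          ),
                          cat_item_probs = c(0.24, 0.18, 0.16, 0.16, 0.14, 0.12)) {
  cfg <- list(
    n_copd = as.integer(n_copd), n_control = as.integer(n_control),
    seed = as.integer(seed),
    age_quantiles_per_group = age_quantiles_per_group,
    female_fraction_per_group = female_fraction_per_group,
    race_probs_per_group = race_probs_per_group,
    bmi_quantiles_per_group = bmi_quantiles_per_group,
    fev1fvc_mean_sd_per_group = fev1fvc_mean_sd_per_group,
    fvc_mean_sd = fvc_mean_sd, fvc_floor = fvc_floor,
    comorbidity_prevalence = comorbidity_prevalence,
    cat_item_probs = cat_item_probs
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "lungchaos_cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_copd < 0L || cfg$n_control < 0L || cfg$n_copd + cfg$n_control <= 0L) {
    stop_lungchaos("group sizes must be nonnegative with a positive total",
                   "lungchaos_config_error")
  }
  for (g in c("copd", "control")) {
    assert_quantiles(cfg$age_quantiles_per_group[[g]],
                     paste0("age_quantiles_per_group$", g))
    assert_quantiles(cfg$bmi_quantiles_per_group[[g]],
                     paste0("bmi_quantiles_per_group$", g))
    assert_number(cfg$female_fraction_per_group[[g]],
                  paste0("female_fraction_per_group$", g), 0, 1)
    ms <- cfg$fev1fvc_mean_sd_per_group[[g]]
    assert_number(ms[["sd"]], paste0("fev1fvc sd (", g, ")"), lower = 1e-9)
    rp <- cfg$race_probs_per_group[[g]]
    if (any(rp < 0) || abs(sum(rp) - 1) > 1e-6) {
      stop_lungchaos("race probabilities must be nonnegative and sum to 1",
                     "lungchaos_config_error")
    }
  }
  if (any(cfg$comorbidity_prevalence < 0) || any(cfg$comorbidity_prevalence > 1)) {
    stop_lungchaos("comorbidity prevalences must lie in [0, 1]",
                   "lungchaos_config_error")
  }
  if (!setequal(names(cfg$comorbidity_prevalence), comorbidity_flags)) {
    stop_lungchaos("comorbidity_prevalence must name exactly the supported flags",
                   "lungchaos_config_error")
  }
  assert_number(cfg$fvc_mean_sd[["sd"]], "fvc sd", lower = 1e-9)
  p <- cfg$cat_item_probs
  if (length(p) != 6L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop_lungchaos("cat_item_probs must be 6 nonnegative values summing to 1",
                   "lungchaos_config_error")
  }
  invisible(cfg)
}

# Mean of a normal(mu, sd) truncated to one side of `bound`.
truncated_normal_mean <- function(mu, sd, bound, side) {
  if (!is.finite(bound)) return(mu)
  z <- (bound - mu) / sd
  # hazard ratios computed on the log scale to stay finite in the far tails
  if (side == "upper") {
    mu - sd * exp(stats::dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  } else {
    mu + sd * exp(stats::dnorm(z, log = TRUE) -
                    pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
}

#' Calibrate the location of a one-sided truncated normal to a target mean
#'
#' Finds `location` such that a normal(`location`, `sd`) truncated at `bound`
#' (keeping values below the bound for `side = "upper"`, above it for
#' `side = "lower"`) has expectation `target_mean`. Used so that synthetic
#' FEV1/FVC draws respect the 70% diagnostic cut while reproducing the
#' published group means exactly.
#'
#' @param target_mean Desired mean of the truncated distribution (percent).
#' @param sd Standard deviation of the parent normal.
#' @param bound Truncation bound; `Inf`/`-Inf` disables truncation.
#' @param side `"upper"` keeps values `< bound`; `"lower"` keeps values `> bound`.
#' @return The calibrated location (scalar).
#' @export
calibrate_truncated_location <- function(target_mean, sd, bound,
                                         side = c("upper", "lower")) {
  side <- match.arg(side)
  assert_number(sd, "sd", lower = 1e-12)
  if (!is.finite(bound)) return(target_mean)
  if ((side == "upper" && target_mean >= bound) ||
      (side == "lower" && target_mean <= bound)) {
    stop_lungchaos("target mean lies on the wrong side of the truncation bound",
                   "lungchaos_calibration_error")
  }
  f <- function(mu) truncated_normal_mean(mu, sd, bound, side) - target_mean
  lo <- target_mean - 50 * sd
  hi <- target_mean + 50 * sd
  if (f(lo) * f(hi) > 0) {
    stop_lungchaos("no truncated-normal location attains the target mean",
                   "lungchaos_calibration_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Inverse-CDF draw from a one-sided truncated normal.
rtruncnorm_onesided <- function(n, mu, sd, bound, side) {
  if (!is.finite(bound)) return(rnorm(n, mu, sd))
  z <- (bound - mu) / sd
  u <- runif(n)
  if (side == "upper") {
    mu + sd * qnorm(u * pnorm(z))
  } else {
    mu + sd * qnorm(pnorm(z) + u * (1 - pnorm(z)))
  }
}

generate_group <- function(n, group, cfg) {
  g <- if (group == "COPD") "copd" else "control"
  ms <- cfg$fev1fvc_mean_sd_per_group[[g]]
  side <- if (group == "COPD") "upper" else "lower"
  loc <- calibrate_truncated_location(ms[["mean"]], ms[["sd"]], 70, side)
  fev1_fvc <- rtruncnorm_onesided(n, loc, ms[["sd"]], 70, side)
  # keep ratios physically plausible (the parent normal has negligible mass
  # outside this range at the configured SDs)
  fev1_fvc <- pmin(pmax(fev1_fvc, 5), 99.9)
  fvc <- rtruncnorm_onesided(n, cfg$fvc_mean_sd[["mean"]], cfg$fvc_mean_sd[["sd"]],
                             cfg$fvc_floor, "lower")
  race_p <- cfg$race_probs_per_group[[g]]
  cat_items <- matrix(
    sample(0:5, n * 8L, replace = TRUE, prob = cfg$cat_item_probs),
    nrow = n, ncol = 8L
  )
  colnames(cat_items) <- paste0("cat_", 1:8)
  com <- vapply(
    comorbidity_flags,
    function(fl) rbinom(n, 1L, cfg$comorbidity_prevalence[[fl]]) == 1L,
    logical(n)
  )
  if (n == 1L) com <- matrix(com, nrow = 1, dimnames = list(NULL, comorbidity_flags))
  tibble::tibble(
    group = group,
    age = sample_from_quantiles(n, cfg$age_quantiles_per_group[[g]]),
    sex = ifelse(runif(n) < cfg$female_fraction_per_group[[g]], "female", "male"),
    race = sample(names(race_p), n, replace = TRUE, prob = race_p),
    bmi = sample_from_quantiles(n, cfg$bmi_quantiles_per_group[[g]]),
    tibble::as_tibble(com),
    fvc = fvc,
    fev1_fvc = fev1_fvc,
    fev1 = fvc * fev1_fvc / 100,
    tibble::as_tibble(cat_items),
    cat_total = as.integer(rowSums(cat_items))
  )
}

#' Generate a synthetic study cohort
#'
#' Draws `n_copd + n_control` subjects with demographics, comorbidity flags,
#' spirometry and CAT responses per the configuration. Every COPD subject has
#' FEV1/FVC < 70 and every control > 70, FEV1 is derived exactly as
#' FVC x FEV1/FVC / 100, and the whole table is a deterministic function of
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"COPD"`/`"control"`), demographics, logical comorbidity flags,
#'   `fvc`, `fev1`, `fev1_fvc` (percent), CAT items `cat_1`..`cat_8` and
#'   `cat_total`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_copd = 3, n_control = 3, seed = 1))
#' table(cohort$group)
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "lungchaos_cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_cohort_config(config)
  withr::with_seed(config$seed, {
    copd <- if (config$n_copd > 0) generate_group(config$n_copd, "COPD", config)
    ctrl <- if (config$n_control > 0) generate_group(config$n_control, "control", config)
  })
  cohort <- dplyr::bind_rows(copd, ctrl)
  cohort <- dplyr::mutate(
    cohort,
    subject_id = sprintf("S%03d", dplyr::row_number()),
    .before = 1
  )
  cohort
}
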