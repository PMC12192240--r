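# lungchaos

Nonlinear-dynamics classification of chronic obstructive pulmonary disease
(COPD) from two-site mobile-phone lung auscultation.

Spirometry — the diagnostic gold standard, COPD defined by FEV1/FVC < 0.70 —
needs equipment and trained staff. An alternative is to record lung sounds
with an ordinary phone at two sites (sustained phonation, "egophony", at the
right supraclavicular fossa; two normal breaths at the left axillary line)
and classify the *dynamics* of the sound. `lungchaos` implements that whole
chain as a tested, reproducible R package:

* a **synthetic study generator**: a 52 COPD / 56 control cohort with
  published-table demographics, spirometry (mean-calibrated truncated
  normals respecting the 70% cut) and CAT questionnaire responses, plus
  two 10-second recordings per subject whose source is a Roessler flow in a
  group-specific chaotic regime, envelope-modulated per site and measured at
  30 dB SNR;
* WAV I/O (mono 16-bit PCM) and deterministic conditioning (DC removal,
  anti-alias decimation 44.1 kHz → 4410 Hz, peak normalization);
* a **300-portrait phase-space library** (band-pass x transform x delay
  grid: delay pairs, value-vs-slope derivative portraits, second
  differences), each portrait summarized by its Shannon **occupancy
  entropy** (bits on a 32x32 robust-range histogram);
* an unsupervised **entropic collapse**: select the pair of portrait
  columns minimizing standardized-histogram entropy (clustered/bimodal
  columns score lowest) — labels are never consulted;
* per-site and composite **ridge-IRLS logistic classifiers** on a
  case-clustered 80/20 split (108 cases → 86 train / 22 test), evaluated by
  AUC, sensitivity and specificity at the train-side Youden threshold, plus
  subgroup accuracies and cohort group-comparison statistics;
* **chaos validation** per recording: Rosenstein maximal Lyapunov exponent
  (MLE, nats/sample) and Grassberger-Procaccia correlation dimension
  (Dcorr) with automated scaling-region selection — the premise being
  MLE > 0 (chaotic) and Dcorr < 2.5 (low-dimensional);
* close-returns diagnostics for unstable periodic orbits, ggplot2
  `autoplot()` methods, broom-style `tidy()`/`glance()`.

## Worked example

```r
library(lungchaos)

res <- run_pipeline(pipeline_config())   # default study, ~7-8 min on one core
print(res)
#> <lungchaos_result> 108 subjects (52 COPD / 56 control)
#>   composite AUC: train 1.000, test 1.000
#>   chaos: max Dcorr 2.39, min MLE 0.0105 nats/sample (216 recordings)

res$collapse$egophony
#> <lungchaos_collapse> site=egophony  selected p108 + p282 (objective 2.371 bits, exhaustive)
```

What those numbers mean: across all 216 synthetic recordings the estimated
correlation dimension stays below 2.5 and the maximal Lyapunov exponent
stays positive — every recording looks like low-dimensional chaos, which is
the generator's contract and the analysis' premise. The entropic collapse
picked two named portraits per site (here portrait 108 and 282 for
egophony) whose entropy columns are strongly bimodal across the cohort; the
composite logistic model fitted on 86 training cases then separates COPD
from control perfectly on both the training cases and the 22 held-out test
cases (AUC 1.0) — the synthetic class effect is encoded purely in attractor
geometry, and the pipeline recovers it without ever showing labels to the
feature-selection stage.

```r
glance(res)
#> # A tibble: 1 x 7
#>   n_subjects n_recordings composite_train_auc composite_test_auc max_dcorr min_mle min_subgroup_test_accuracy
#> 1        108          216                   1                  1      2.39  0.0105                          1

dplyr::filter(res$group_comparisons, variable %in% c("fev1_fvc", "cat_total"))
#> fev1_fvc   57.9 (52.6-63.2) vs 78.7 (73.8-83.5)   mann_whitney  p = 3.6e-19
#> cat_total  18.0 (13.8-21.0) vs 17.0 (14.0-21.2)   mann_whitney  p = 0.87
```

The cohort reproduces the study's statistical fingerprint: spirometry
separates the groups overwhelmingly while CAT symptom scores do not.

A thin command-line wrapper with `simulate` / `analyze` / `run` /
`validate` subcommands is installed at `inst/cli/lungchaos.R`.

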