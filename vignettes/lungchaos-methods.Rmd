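---
title: "Chaos-based auscultation analysis for COPD classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-based auscultation analysis for COPD classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modeling idea

Chronic obstructive pulmonary disease (COPD) is diagnosed by spirometry
(FEV1/FVC < 0.70), which needs trained staff and equipment. An alternative is
to record lung sounds with an ordinary mobile phone at two auscultation
sites — sustained phonation ("egophony", the patient voicing *e* for a full
breath, repeated) at the right supraclavicular fossa, and two normal tidal
breaths at the left axillary line — and to classify the *dynamics* of those
sounds rather than their loudness or spectrum.

The working hypothesis is physical: airflow through airways is a biofluid
system whose acoustic observable behaves like a low-dimensional, weakly
chaotic flow, and obstructive disease changes the geometry of the underlying
attractor. `lungchaos` implements that analysis chain end to end:

1. condition each recording (DC removal, anti-alias decimation from
   44.1 kHz to 4410 Hz, peak normalization);
2. map it to a library of 300 two-dimensional **phase-space portraits**
   (band-pass filter x transform x delay grid);
3. summarize every portrait by its **Shannon occupancy entropy** (bits on a
   32 x 32 robust-range histogram) — one 300-vector per recording;
4. **collapse** the cohort's recordings x portraits matrix to two named
   portrait columns by unsupervised minimum-entropy selection;
5. fit per-site and composite (4-feature) ridge-regularized logistic models
   on the training side of a case-clustered 80/20 split;
6. report AUC / sensitivity / specificity on both sides, subgroup
   accuracies, and cohort group comparisons;
7. validate the dynamical premise per recording with the Rosenstein maximal
   Lyapunov exponent (MLE) and the Grassberger-Procaccia correlation
   dimension (Dcorr).

Because the study recordings this design emulates are not public, the package
ships a first-class synthetic data generator; every stage is tested against
it and against closed-form or brute-force oracles.

## The synthetic cohort

`generate_cohort()` draws 52 COPD and 56 control subjects by default.

* **Ages and BMI** are sampled through piecewise-linear quantile functions
  through the published five-number summaries (COPD age median 63, IQR
  56–70; control 57.5, IQR 39–66.5; global range 19–85; BMI range
  11.6–65.4 kg/m²). Only summaries are published, so any distribution
  matching them is admissible; the piecewise-linear quantile function is the
  simplest such choice.
* **FEV1/FVC** must satisfy two constraints at once: the hard diagnostic cut
  (COPD < 70%, control > 70%) and the published group means (56.30 ± 10.47
  and 79.52 ± 9.75). We therefore draw from one-sided truncated normals whose
  *location* is calibrated with `calibrate_truncated_location()` (bisection on
  the closed-form truncated-normal mean, stable log-scale hazards) so that the
  truncated mean equals the target exactly. FVC is group-shared
  (mean 2.80 L, SD 0.90, floored at 0.5 L) because the study found no
  significant FVC difference, and FEV1 is derived exactly as
  FVC x FEV1/FVC / 100.
* **Comorbidities** are independent Bernoulli flags at the published
  prevalences (e.g. asthma 33/108, hypertension 58/108, tobacco-ever
  80/108). **CAT items** share a single distribution over scores 0–5 across
  groups and items, calibrated so the total score's median is near 16 — the
  study found no group differences in CAT, so a shared distribution is the
  faithful emulation.

## The synthetic recordings

The study reports only that its recordings are low-dimensional
(Dcorr < 2.5) and likely chaotic (MLE > 0); nothing else about their signal
structure is published. The generator therefore uses the most conservative
emulation: a Roessler flow, the textbook minimal chaotic system, with the
class effect placed **in the attractor geometry** — the bifurcation
parameter is c = 5.7 for COPD and c = 6.5 for controls (a = b = 0.2 for
both) — rather than in amplitude or spectrum, so that the portrait-entropy
features, not trivial loudness, must carry the diagnostic signal. Both
regimes are verified chaotic by the packaged estimators in the test suite;
c values near 6.0 sit in a periodic window of the Roessler family and are
avoided.

Details, all configurable in `acoustic_config()`:

* **Time scale.** 800 flow time-units per second of audio, placing the
  orbital fundamental near 135 Hz — phonation range. One RK4 step per
  44.1 kHz output sample (h ≈ 0.018 time units) integrates the flow; 100
  time units of transient are discarded.
* **Envelopes.** Egophony: repeated plateau–release phonation cycles
  (period 4.3 s, rise 0.15 s, release 0.35 s, floor 0.12). Axillary: two
  tidal-breath cycles (sin² envelope, period 5 s, floor 0.30). Floors keep
  the dynamics observable between breaths; the axillary floor is the larger
  because deep amplitude modulation smears the attractor's scale structure
  and inflates the apparent correlation dimension.
* **Noise.** The enveloped observable is peak-normalized to 0.95 and
  measurement noise is added at 30 dB SNR; if noise pushes any sample past
  ±1 the signal is rescaled to 0.999 so the 16-bit WAV invariant holds.
* **Durations.** The study does not state recording lengths; 10 s per
  recording, one recording per site per subject, is our declared default
  (the pipeline tolerates repeats by averaging coordinates per case).

What this generator deliberately does **not** emulate: vocal-tract
resonances and formants, heart sounds, device/microphone transfer functions,
inter-subject anatomical variability beyond the label effect, and ambient
noise. Passing tests on synthetic data therefore demonstrate that the
*pipeline* is correct and self-consistent — that the estimators detect the
dynamics that are present and that the classifier recovers a
geometry-encoded class difference — not that real lung sounds are this
clean or this separable.

## Portraits and occupancy entropy

The original portrait identities are proprietary; the package replaces them
with an open, documented grid: 10 frequency bands (broadband plus nine
band-passes between 30 and 2000 Hz) crossed with three transforms —
delay pairs (27 lags from 1 to 64 samples), value-versus-slope derivative
portraits (4 smoothing windows), and second differences — enumerated
deterministically and truncated to 300 entries.

Occupancy entropy is computed on a 32 x 32 histogram spanning the 1st–99th
percentile range per axis (outliers clamped to edge cells), which makes the
feature invariant to amplitude scaling. Portraits are evaluated on the
leading 16384 conditioned samples (~3.7 s): entropy estimates stabilize well
before that, and the cap keeps a full 216-recording featurization inside a
few minutes on one core.

## The entropic collapse

The published description of the dimension reduction is one sentence: an
unsupervised "entropic metaheuristic" that keeps the most important dynamics
without fitting the outcome, with minimum entropy corresponding roughly to
maximum variance. We implement the reading that makes that sentence
coherent: after standardizing each feature column, bin it on [−3, 3] with 16
equal-width bins and compute Shannon entropy; a clustered or bimodal column
concentrates its mass in few bins and scores *low*, while an uninformative
unimodal column scores high. The collapse selects the **pair of columns
minimizing the entropy sum** — exhaustively up to 400 columns, greedily
beyond — with ties broken toward the lowest portrait ids. Selection (rather
than a learned linear combination) preserves interpretability: each retained
dimension is one named portrait. Labels are never consulted; a test asserts
the output is bit-identical under label permutation. Constant columns return
an infinite sentinel and are excluded.

## Classifiers and evaluation

Splits are case-clustered: subjects are shuffled under the split seed and
the first `round(0.8 n)` (half away from zero; 108 → 86/22) go to training;
recordings follow their subject. The logistic models are fitted by
iteratively reweighted least squares on a ridge-penalized likelihood
(penalty 1e-6 on standardized slopes, intercept unpenalized, step-halving,
convergence at max coefficient change < 1e-8 or 100 iterations). The tiny
ridge changes well-conditioned fits by less than 1% (tested) but keeps
coefficients finite when the synthetic classes are perfectly separable —
which they frequently are. The composite model is a fresh fit on the
concatenated 4-D per-case coordinates of both sites, not an average of
per-site probabilities: "a single composite model" implies one model over
both sources.

AUC uses the exact Mann-Whitney rank formulation (tested equal to
trapezoidal integration at 1e-12 and against pROC). The operating threshold
is the train-side Youden point (lowest maximizer of J), reused unchanged on
the test side; the published work does not state its operating-point rule,
so this choice is declared, and threshold hygiene (test side never touches
threshold selection) is enforced by a test. Subgroup accuracies use the
composite model at that threshold; subgroups with empty test sides report
missing, not zero. Group comparisons use Mann-Whitney for continuous
variables (exact when both n ≤ 10 and untied), chi-squared for binary ones,
and Fisher's exact test when any expected cell is below 5; p-values are
reported raw, with no multiplicity correction, matching the descriptive use
of these tables.

## Chaos estimators

* **MLE (Rosenstein).** Embedding dimension 5; delay chosen per recording as
  the first interior minimum of the binned average mutual information (a
  minimum must drop below 80% of the lag-1 value, rejecting the jitter of
  flat MI curves; fallback: first autocorrelation crossing of 1/e, then
  lag 1). Theiler window 2 x delay for both estimators. 400 reference
  points (deterministic, evenly spaced) are paired with their nearest
  neighbours over a strided candidate grid; the exponent is the
  least-squares slope of the mean log separation over offsets
  1..(delay x dimension), in nats per sample. Rosenstein is preferred over
  Wolf for robustness at desk-scale lengths.
* **Dcorr (Grassberger-Procaccia).** Correlation sums on a 20-point
  geometric radius grid spanning 0.07–2.8 signal standard deviations, 1500
  deterministically subsampled points with Theiler-excluded pairs. The
  scaling region is chosen automatically: the contiguous window of at least
  5 radii maximizing linear-fit R² subject to C(r) within [1e-4, 1e-1].
  Automating the window makes results reproducible where the literature
  leaves the region choice to the analyst. The radius floor sits above the
  30 dB measurement-noise ball so the fit sees attractor scaling, not noise.
* **Outliers.** Low-R² fits are reported in the diagnostics, never excluded
  automatically, following the study's own practice of flagging but keeping
  its one outlier.

Oracles in the test suite: the logistic map (estimate within 5% of the
derivative-sum exponent ln 2 across seeds), sinusoids (|MLE| < 0.01;
Dcorr ≈ 1), uniform planar noise (Dcorr ≈ 2, cross-checked against a direct
pair-counting slope), the Hénon map (stability under point-budget changes),
and i.i.d. noise in dimension 5 (Dcorr > 2.5, confirming noise is not
mistaken for low-dimensional structure).

## Problem sizes and determinism

The default study — 108 subjects, 216 ten-second recordings analyzed at
4410 Hz with the 300-portrait library — runs end to end, including both
chaos estimators on every recording, in roughly ten minutes on one core.
The tests use the same default study once (cached across test blocks) plus
much smaller smoke configurations. A single master seed fans out into
derived per-stage streams (cohort, each recording, split), so a result is a
pure function of its configuration; the estimators use no randomness at all.

## Known limitations

* The portrait library, collapse objective, and operating-threshold rule are
  open reconstructions of one-sentence descriptions; they are validated as a
  coherent pipeline on synthetic data, not claimed to reproduce the
  proprietary implementation.
* The synthetic classes are cleanly separable by construction; real-data
  performance claims cannot be transferred from these tests.
* The greedy collapse path coincides with the exhaustive optimum because the
  objective is additive across columns; the machinery allows non-additive
  objectives later, where greedy would genuinely approximate.
* No surrogate-data hypothesis testing or full Lyapunov spectrum; MLE > 0
  plus Dcorr < 2.5 is the premise check the design calls for, not a formal
  chaos proof.
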