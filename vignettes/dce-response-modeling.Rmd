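---
title: "Modeling osteosarcoma chemotherapy response from DCE-MRI perfusion features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling osteosarcoma chemotherapy response from DCE-MRI perfusion features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteodce)
```

## The problem

Osteosarcoma is treated with neoadjuvant chemotherapy before resection, and
the fraction of viable tumor in the resected specimen — good response below
10% viable cells, poor response at or above 10% — is the prognostic
reference standard. Dynamic contrast-enhanced (DCE-)MRI probes tumor
vascularization: after a gadolinium bolus, viable tumor enhances early and
fast, while chemotherapy-induced necrosis and fibrosis enhance late and
weakly. Comparing perfusion before and after chemotherapy therefore carries
a non-invasive response signal that is available before surgery.

`osteodce` implements the full analysis chain: semi-quantitative feature
extraction from time-intensity curves (TICs), relative-change features
across the pre/post pair, cross-validated logistic-regression model
selection, threshold derivation, batch harmonization for a second center,
and external validation — together with a synthetic cohort generator so
every stage is testable without patient data.

## Time-intensity curves and perfusion features

A TIC is the mean ROI signal per dynamic frame. Acquisition starts 6 s
before injection; the first minute is sampled at 1 s and minutes 2–5 at
3–4 s (`make_sampling_grid()`). Two tumor ROI strategies are supported:

* **whole slab** — the entire tumor on the single slice of largest tumor
  area;
* **focal area** — two circular ROIs of 10–20 mm² in the earliest and
  fastest enhancing tumor regions, features averaged. Because the visual
  placement this emulates is subjective, `place_focal_rois()` defines a
  deterministic proxy: per-pixel onset (the same 20% rule as below) on the
  3×3-smoothed subtraction stack, ranked by earliest onset, then largest
  wash-in slope, with row-major order as the final tie-break. When onsets
  do not differ across the tumor, ranking falls back to the most intense
  enhancement, mirroring the visual fallback. Discs are "nearest-n-pixels"
  discrete circles, so a 15 mm² request on a 1 mm grid is exactly 15
  pixels.

Four features are computed per scan:

* **T0, onset of enhancement** — the first sample whose signal exceeds the
  mean of *all earlier samples* by more than 20%. The definition is
  self-referential; `detect_t0()` resolves it with a left-to-right scan in
  which the candidate baseline grows until the rule fires. At least two
  baseline samples are required, so a spike in the opening frames cannot
  trigger. A curve where the rule never fires is flagged non-enhancing.
* **TTE, time to enhancement** — tumor T0 minus regional-artery T0. The
  bolus reaches the artery first, so TTE is normally positive; negative
  values are returned with a warning.
* **WIR, wash-in rate** — maximum rise per second between onset and peak,
  as a fraction of baseline. The default estimator maximizes over
  consecutive sample pairs (including the pair *ending* at the onset
  sample, so an instantaneous jump yields `jump/(dt × baseline)`). On
  noisy curves this maximum inherits an order-statistic bias — the max of
  ~20 noisy single-pair slopes sits well above the true slope — so a
  noise-robust `rise_chord` estimator is provided: the chord from the
  onset sample to the first sample within three baseline-noise standard
  deviations of the peak. Both coincide on noiseless piecewise-linear
  curves; parameter-recovery tests use the chord form.
* **MRE, maximum relative enhancement** — peak over baseline. The default
  convention is the net enhancement fraction `(max − baseline)/baseline`;
  the raw ratio `max/baseline` differs by the additive 1 and is available
  behind a switch. Only relative features enter the model, and the two
  conventions give different rMRE, so the choice is explicit.
* **AUC** — trapezoidal integral of `(si − baseline)/baseline` from T0 to
  the last acquired sample (≈5 min), honoring the irregular grid. The
  integration window and the integrand (`net` vs `ratio`) are switches;
  the net integrand from T0 to the end of acquisition is the default.

Feature normalization needs a baseline signal. T0 detection always uses
its self-consistent growing baseline, but WIR/MRE/AUC divide by the mean
over the curve's *pre-injection window* when the acquisition timing is
known, falling back to the pre-T0 window otherwise. On a slow linear rise
the detected T0 lies a few samples into the rise, so a pre-T0 mean would
be contaminated by early enhancement; the pre-injection window is the
cleaner estimate of non-enhanced signal.

### Relative-change features

Ratios divide pre- by post-chemotherapy values — `rWIR`, `rMRE`, `rAUC`
— so a strong responder (perfusion collapses) has large ratios; `ΔTTE` is
post minus pre (onset drifts later when the tumor devascularizes); and
`rVolume` is the pre/post ratio of ellipsoid volumes `(π/6) d₁d₂d₃` from
three orthogonal diameters. A completely non-enhancing post scan (total
response) is censored rather than dropped: rate and enhancement features
are floored at `eps = 1e-6` (baseline-relative units) so ratios stay
finite and land far on the good-response side, and the post onset is
censored at the end of acquisition, making TTE `t_end − artery T0`. If
exactly one focal ROI is non-enhancing, the focal average uses the same
conventions.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
two levels.

**Feature level.** Each patient draws a response label
(Bernoulli, default 27/55 poor) and correlated relative features from
class-conditional distributions calibrated to the published
training-cohort summaries: lognormal for ratio features (positive and
right-skewed — the same reason the modeling step log-transforms) with the
class median as the lognormal median and a log-scale SD of
`log(q3/q1)/1.349` from the printed IQRs; normal with IQR-matched SD for
ΔTTE, which spans negatives. Whole-slab rWIR defaults to medians 4.81
(good) vs 0.69 (poor). Co-movement between features is a Gaussian copula
with equicorrelation 0.6 — the analysis implies but never quantifies this
correlation, so it is a configurable default. Diameters are drawn so that
the ellipsoid-volume ratio equals the drawn rVolume exactly.

**Curve level.** Optionally each patient also gets pre/post tumor and
artery TICs from a piecewise enhancement model — flat baseline, linear
rise, exponential washout — the simplest shape exposing all four features.
The post curve realizes the drawn rWIR, rMRE and ΔTTE exactly in its
noiseless parameters (wash-in slope divided by rWIR, peak enhancement by
rMRE, onset shifted by ΔTTE against a fixed artery whose onset precedes
the tumor's by a 2–8 s delay); rAUC is emergent rather than imposed,
since AUC is not a free parameter of this curve family. Gaussian noise of
2% of baseline is added per sample.

The generator does **not** emulate: T1 saturation or any signal-to-
concentration nonlinearity, motion, registration error between pre and
post scans, 3D anatomy, observer segmentation variability, or
center-specific protocol differences beyond a log-scale location/scale
shift (`apply_center_effect()`). Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes — not performance on real
scanner data.

## Response modeling

All features are log-transformed (natural log for ratios; the signed log
`sign(x)·log1p(|x|)` for ΔTTE, which a plain log cannot handle — its
class IQRs span negatives). Model candidates are capped at two features:
every feature alone, every pair of perfusion features within a
segmentation method, and every perfusion feature paired with rVolume — 29
candidates.

Each candidate is scored by stratified 5-fold cross-validation repeated 50
times with fresh shuffles (stratification protects the near-balanced
49%/51% class split at n = 55). Within every split, features are z-scored
using *training-fold* parameters only and a logistic model (IRLS, poor
coded 1) is fitted on the training fold; the validation fold contributes
ROC AUC plus accuracy/sensitivity/specificity at probability 0.5. A small
ridge penalty (λ = 1e-4 on slopes, never the intercept) guards against
the quasi-separation that a strongly separating feature produces at this
sample size; λ = 0 reproduces the plain ML fit.

Fold scores are positively correlated because training sets overlap, so
95% CIs use the corrected resampled t-test: mean ±
`t_{J−1} · sqrt(var · (1/J + n_test/n_train))` with J = 250 fold scores.
The correction term `n_test/n_train = 1/4` roughly quintuples the naive
variance.

Selection maximizes mean AUC; ties go to fewer features, then alphabetical
feature names, making selection invariant to candidate order. The final
model is refitted on the whole training cohort and its probability
threshold fixed by Youden's index on the full-training predictions
(candidate cuts are midpoints between adjacent distinct probabilities plus
the two degenerate cuts, so the maximized J is never negative; ties
resolve to the more sensitive cut). In-fold accuracies use 0.5 while the
frozen threshold is Youden-optimal — the protocol leaves this open, and
both numbers are reported. For a single-feature model the probability
threshold is inverted through the logistic link, the training z-score and
the log, giving a natural-scale cutoff such as "rWIR below t predicts
poor response"; `ratio_to_percent_decrease()` re-expresses a ratio cutoff
as a percent WIR decrease (ratio 2.3 ↔ 57% after integer rounding).

## Harmonizing a second center

The external cohort is harmonized *into the training frame* with a
reference-batch variant of ComBat: features are standardized with
location/scale (and optional covariate effects) estimated on the
reference batch only, per-batch location/scale deviations are shrunk by
parametric empirical Bayes (normal prior on locations, inverse-gamma on
scales, moment-matched hyperparameters, iterative update to 1e-6), and
reference rows pass through bit-identical. Parametric priors suit the
small batch (30 patients); the fit operates on the log scale the model
uses. The response label is included as a preserved covariate by default
— without it, a class-composition difference between cohorts (49% vs 63%
poor) would be misread as a center effect and removed; the design is
configurable since the original protocol does not state one. The
fit/apply split yields a serializable model applicable to new rows of a
known batch, and validation runs once with and once without
harmonization.

## Cohort statistics

Interobserver agreement uses the single-rater, two-way random-effects,
absolute-agreement ICC(2,1) from the two-way ANOVA decomposition with an
F-based 95% CI; absolute agreement penalizes a systematic offset between
observers, which is the relevant notion for feature reproducibility. The
form is switchable to consistency ICC(3,1) since the protocol does not
state it. Class comparisons use the Kruskal-Wallis test (midranks,
standard tie correction), which with two groups is the asymptotic
rank-sum comparison.

## Numerical choices and degenerate inputs

* `eps = 1e-6` (baseline-relative units) floors denominators of ratio
  features and censors non-enhancing scans.
* Subtraction images clip negative differences at zero with a warning:
  they exist to visualize enhancement, and negative enhancement is noise.
* Onset detection requires ≥3 samples and ≥2 baseline samples; a zero
  baseline raises a degenerate-baseline error rather than dividing by 0.
* Zero-variance features abort normalization and ComBat standardization
  (degenerate-feature errors); single-class outcomes abort fitting and
  thresholding.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  cohorts, curves and CV fold assignments are byte-reproducible; the
  focal-ROI placement and model selection are fully deterministic given
  their inputs.
* Pixel spacing defaults to 1×1 mm when a series carries no geometry.

## Problem sizes used by the test suite

The suite exercises the study-sized design throughout: training cohorts of
55 patients (27/55 poor), external cohorts of 30 (19/30 poor), 5-fold ×
50-repeat CV. Distributional checks use n = 2000 cohorts for median
calibration (10% tolerance), 20 seeds for signal recovery (mean CV AUC of
the whole-slab rWIR model ≥ 0.85 and a natural threshold strictly between
the class medians in ≥ 18/20 seeds), 10 permutation seeds for the null
control (10-seed mean AUC within 0.5 ± 0.07 — a *single* permutation of
55 labels retains chance association with AUC spread ≈ 0.1, so a per-seed
band that tight would be a statistical impossibility rather than a test),
and matched-composition n = 200 cohorts for the shift-removal property of
harmonization, where empirical-Bayes sampling noise at n = 30 would
otherwise mask the ≥90% reduction being verified.

## Known limitations

The enhancement model is piecewise linear-exponential, not a
pharmacokinetic (Tofts-type) model — no T1 mapping, arterial input
deconvolution, Ktrans or ve. IQR calibration of the generator is
approximate: a lognormal matched to the median and IQR spread does not
reproduce asymmetric printed IQRs exactly, particularly for ΔTTE.
Registration, motion and segmentation variability are out of scope;
masks are inputs. The natural-scale threshold learned on a synthetic
cohort varies with the draw — what is stable, and what the tests assert,
is that it falls between the class medians and that the ComBat-harmonized
external validation is at least as accurate as the raw one under a center
shift.
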