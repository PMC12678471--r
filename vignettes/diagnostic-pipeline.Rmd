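---
title: "Methods: quantitative ultrasound + serum MMP-7 diagnostics for biliary atresia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ultrasound + serum MMP-7 diagnostics for biliary atresia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biliary atresia (BA) is a neonatal obliterative cholangiopathy that must be
separated from other causes of infant cholestasis quickly: the corrective
Kasai portoenterostomy works best when performed early, while the definitive
diagnostic standard (intraoperative cholangiography) is invasive. Two
minimally invasive signals carry most of the usable information: grayscale
ultrasound of the gallbladder and of the "triangular cord" — echogenic
fibrous tissue at the porta hepatis — and serum matrix metalloproteinase-7
(MMP-7), an ELISA biomarker markedly elevated in BA.

`badx` implements a full quantitative pipeline over these two modalities:
feature extraction from ultrasound regions of interest (ROIs), an
age-stratified MMP-7 decision rule, lasso-selected logistic models for each
modality and their combination, and a diagnostic-accuracy evaluation suite.
Because real sonograms and patient-level data of this kind are not publicly
deposited, the package ships a synthetic generator that emulates the study
structure end-to-end; everything below runs on that material.

## Image preprocessing and features

Images are read as grayscale matrices on the 0–255 scale (RGB collapsed by
Rec. 601 luminance, 0.299 R + 0.587 G + 0.114 B). Each image is then
normalized so that its pixel mean is 55 and its interquartile range (IQR)
is 40:

$$x' = \frac{x - \bar{x}}{\mathrm{IQR}(x)} \cdot 40 + 55.$$

The two constants are fixed properties of the pipeline; their purpose is to
place images from different ultrasound devices on one intensity scale, and
any feature computed after normalization is invariant to positive affine
rescaling of the raw input. Two numerical choices are deliberate:

* **Quartile rule.** The IQR uses linear interpolation between order
  statistics (`stats::quantile` type 7). Only the normalization *targets*
  are pinned down by the method; the interpolation rule is exposed in
  `norm_config()` and documented so that the mapping is reproducible.
* **No clipping.** Normalized values may leave \[0, 255\] and are kept as
  real numbers. Clipping would silently break the mean-55/IQR-40 guarantee;
  quantization to 8 bits happens only when an image is written to PNG.

Near-constant images (IQR = 0) cannot be normalized and raise a classed
error naming the offending source.

ROIs are supplied as manual crop boxes (0-based, row-major, half-open, the
convention stated in the annotation schema). Cropping is pure submatrix
extraction, never resampling. Boundary delineation then runs a fixed-order
morphological pipeline on the cropped, normalized image:

1. Gaussian smoothing (σ = 2 px),
2. global Otsu threshold,
3. polarity selection — keep pixels *below* the threshold for the
   fluid-dark gallbladder, *above* for the echogenic triangular cord,
4. morphological opening, then closing (disk structuring element,
   radius 3 px),
5. retention of the largest connected component (8-connectivity),
6. hole filling.

All of these are artifact choices exposed in `morph_config()`; nothing in
the underlying method fixes them, and the defaults were chosen once on
high-contrast phantoms. A failed delineation (constant crop, empty mask) is
a classed signal, and the view is treated as missing downstream — it is
never silently imputed at this stage.

From each crop/mask pair, `extract_view_features()` computes three feature
families for both the masked ROI and the whole crop: quantiles at levels
{0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95} plus mean and median (grayscale),
the standard deviation of pixel intensities (texture; population convention,
divide by *n*), and the absolute mask area with its ratio to the crop area
(size). The quantile levels are a package default — the method calls only
for "quantile values" — and are configurable.

A patient's three views (gallbladder, triangular cord at the portal-vein
branches, transverse right portal vein) are concatenated with per-view
availability indicators. Patients with **no** usable view are excluded with
an explicit signal listing their ids (the "at least one ROI visible"
inclusion rule); missing views are imputed with training-set medians while
their indicator stays 0.

## Serum MMP-7

Concentrations are the arithmetic mean of 1–3 ELISA replicates; when
readings are flagged as pre-dilution instrument values they are multiplied
by the dilution factor (default 20-fold). Inputs are otherwise assumed to be
final serum concentrations — the dilution handling is explicit because
reported values in this field are sometimes back-calculated upstream and
sometimes not.

The binary positivity rule is age-stratified with *strict* inequalities:
positive means > 18 ng/mL for infants older than 30 days and > 28.1 ng/mL at
30 days or younger. Age exactly 30 days belongs to the younger stratum. The
strictness at the cutoff value itself is taken literally from the rule's
statement; it matters only for concentrations exactly at a threshold.

## Diagnostic models

All numeric features are min–max scaled to \[0, 1\] with bounds learned on
training data. Validation data are transformed with the *training* bounds
and not clipped — an out-of-range case keeps its distance from the training
hull rather than being folded onto its edge. Constant training features are
dropped with a warning.

Variable selection uses the lasso (L1-penalized logistic regression,
`glmnet`), with the penalty chosen at the minimum of stratified 5-fold
cross-validated binomial deviance under a recorded fold seed. The selected
set is then refit by *unpenalized* maximum-likelihood logistic regression:
selection and estimation are split so that reported coefficients are not
shrunken. Neither the fold count, the loss, nor the penalized-vs-refit
choice is fixed by the underlying method; these are the package's choices,
recorded in every model's metadata. Under perfect separation the MLE
diverges and the fit falls back to a tiny-ridge-stabilized estimate
(λ = 10⁻³) with a classed warning.

Three model kinds share this pipeline:

* `us_only` — ultrasound features alone (lasso + refit);
* `mmp7_only` — a two-variable logistic model on log10(1 + MMP-7) and the
  age-stratum indicator, no selection step. The marker enters
  *continuously*: a binary-rule-only model cannot produce the graded risk
  scores on which the reported ROC analyses of serum MMP-7 rest. The binary
  rule remains available separately as `mmp7_positive()`;
* `combined` — ultrasound features plus the two MMP-7 terms, full pipeline.
  Patients lacking MMP-7 are excluded from combined training with a logged
  warning (MMP-7 is mandatory for the combined prediction, as in the
  intended clinical use).

The probability cutoff is chosen on training scores by exhaustive
enumeration of the Youden index (sensitivity + specificity − 1) over all
midpoints between consecutive distinct scores; ties break toward the lower
cutpoint, i.e. toward higher sensitivity — the clinically safer direction
for a disease where a missed case delays time-critical surgery. A fixed
cutoff method is also supported. Models serialize to JSON at 17 significant
digits, which round-trips doubles bit-for-bit.

## Evaluation statistics

* **AUC** is the tie-corrected rank statistic (concordant pairs + ½ ties
  over all case–control pairs), with DeLong structural-components variance
  for the 95% CI (truncated to \[0, 1\]) and the paired DeLong z-test for
  model comparisons. Two identical score vectors have zero-variance
  difference; that degenerate comparison is defined as difference 0, p = 1.
* **Sensitivity/specificity/accuracy** are exact count ratios with
  Clopper–Pearson exact binomial CIs. The exact method is a deliberate
  choice — proportion-CI conventions differ across clinical reports, and
  the conservative exact interval is the defensible default. Percentages
  are formatted to one decimal, rounding half away from zero (matching
  clinical-report style, not banker's rounding).
* **Calibration** uses equal-frequency decile bins of predicted
  probability, comparing per-bin mean prediction with observed event
  fraction. Tied predictions can collapse bins; counts always sum to n.
* **Subgroup reports** reuse the same trained model and threshold within
  each group (e.g. internal vs external centers); a one-class subgroup gets
  confusion metrics but no AUC, with a warning.
* **Cohort comparisons** use Pearson's chi-squared (no continuity
  correction) for categorical variables and the Wilcoxon rank-sum test for
  continuous ones, formatted as n (%) and median (Q1, Q3). P-values are
  unadjusted.

## The synthetic generator

`generate_cohort()` draws labels independently at a configurable prevalence
(training-style default 187 patients at 29.9%; validation-style 161 at
62.1%), then ages, MMP-7 and biochemistry from class-conditional
distributions. Choices worth stating:

* **MMP-7 is log-normal per class** — a positive, right-skewed biomarker —
  with default class medians 8 vs 40 ng/mL (sdlog 0.8) chosen so that the
  medians straddle both positivity cutoffs and the single-marker AUC lands
  near 0.92, a realistic magnitude for this marker.
* **Ages are discrete-uniform on 20–120 days** so both MMP-7 age strata
  occur; eligibility is capped at 150 days.
* **One RNG stream per patient**, derived from (master seed, patient
  index): patient i's record is identical whether 10 or 10,000 patients are
  generated, which makes subsets and reruns reproducible.

`generate_image()` builds speckle phantoms: Gaussian noise (sd 12) on a
smooth background (mean 90 with a mild vertical gradient) with one embedded
structure — a hypoechoic ellipse for the gallbladder view, an echogenic
triangle or band for the two triangular-cord views. Class effects scale
structure contrast and size (BA: smaller, fainter gallbladder; strong
triangular cord), and each image additionally draws per-patient log-normal
multipliers on size (sd 0.2) and contrast (sd 0.35). That last dial is what
makes the problem statistically honest: without per-patient biological
variability the class-conditional feature distributions barely overlap and
every classifier is trivially perfect. With the defaults, held-out AUCs on
the default cohorts land around 0.97 (ultrasound), 0.92 (MMP-7) and 0.99
(combined) — deliberately mirroring the qualitative ordering
MMP-7 < ultrasound < combined rather than claiming any real-data values.

What the generator does **not** emulate: physical acoustic speckle
(multiplicative, correlated), shadowing and other view-dependent artifacts,
operator variability in probe placement and cropping, device- or
center-specific texture beyond a global intensity scale, and any real
anatomical shape variation. Passing tests therefore demonstrate that the
pipeline's machinery is correct and internally consistent on data with
known ground truth — not that the trained weights have clinical validity.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to balance statistical
resolution against desk-scale runtimes: cohort-level checks at n = 187/161
(the default study-shaped cohorts) over 20 seeds for the modality-dominance
property; ablation and dial experiments at n = 100–250 with 96×96 phantoms;
oracle comparisons exhaustively at n ≤ 12 (AUC pair counting), n ≤ 10
(DeLong structural components) and n = 30 with a 20,000-rep permutation
oracle; calibration self-consistency at n = 10,000.

## Known limitations

* The morphological defaults were chosen on phantoms; real sonograms with
  acoustic shadowing or septated gallbladders may need different smoothing
  and structuring-element scales (both are exposed).
* Otsu thresholding assumes a bimodal crop histogram; crops dominated by
  background can return a noise component, which downstream modelling must
  absorb (in practice the lasso tends to discard features from such views).
* The lasso's fold seed is recorded but cross-validation noise means the
  selected feature *set* (not the predictions' quality) can differ between
  seeds.
* The validation-time absence of clipping means a severely out-of-range
  case produces a score extrapolated beyond the training hull; this is
  visible in the scaled feature values and intended, but it is
  extrapolation nonetheless.
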