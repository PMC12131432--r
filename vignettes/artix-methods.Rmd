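---
title: "Methods: finger-redness scoring of Raynaud's phenomenon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finger-redness scoring of Raynaud's phenomenon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artix)
```

## The measurement problem

Raynaud's phenomenon (RP) manifests as episodic digital vasospasm whose
severity is hard to quantify objectively. Infrared thermography of the
rewarming response after a standardized cold challenge is a validated
reference, but requires a thermal camera. A mobile-phone photograph of the
dorsum of the hands records the perfusion-driven colour of the same
fingers. This package computes a per-timepoint finger-redness score
(ARTIX) from such photographs and provides the session model and the
statistical machinery needed to validate it against thermography in an
RP-versus-control design.

The pipeline assumes: hands resting on a dark, roughly uniform background;
both hands visible and roughly flat (fingers not locked in flexion); a
hand-landmark provider supplying the standard 21-point set per hand (wrist
plus four joints per digit). The landmark provider is pluggable — the
synthetic generator supplies exact landmarks, a CSV provider loads
precomputed sets, and an adapter to any external detector can be slotted
in without touching the core.

## Per-frame model

**Segmentation.** Two interchangeable segmenters produce the binary hand
mask. The classical fallback estimates the background palette from the
frame border, thresholds the Euclidean RGB distance to it (default 45
intensity units), then applies morphological closing (disc radius 3 at the
512 px reference resolution, scaled proportionally at other working
resolutions) and keeps the at most two largest connected components. It is
fully deterministic. The trainable segmenter is a per-pixel logistic
classifier on raw and Gaussian-smoothed colour features, fitted by
iteratively reweighted least squares with a small L2 penalty (`lambda =
1e-3`) so the solution stays finite when the classes are perfectly
separable; probabilities are thresholded at 0.5 and cleaned up
identically. Mask agreement is measured as intersection-over-union (IoU),
the stricter of the common overlap readings.

**Finger extraction.** Landmarks are mapped onto the mask grid
(normalized coordinates via `x_px = x (W-1)`; pixel coordinates via the
per-axis shape ratio; 0-based, x = column, y = row, pixel-centre
sampling). Each digit's skeleton is its MCP-to-tip polyline. A mask pixel
joins digit *d* when its projection on the proximal axis lies distal to
the MCP and its distance to the skeleton is at most `r_d = 0.5 x
min(distance to adjacent MCP landmarks)`; pixels eligible for several
digits go to the nearest skeleton, ties to the lower digit index. The
proximal boundary is placed at the MCP joint (rather than the interdigital
web) because the MCP is an actual landmark and needs no extra calibration;
`r_d` is scale-free for the same reason, and the 0.5 factor is
configurable. Thumbs are segmented and labelled but excluded from scoring:
the score is defined over the second to fifth digits of both hands (eight
regions for a two-hand frame), matching the digit convention of the
thermography reference.

**Colorimetry.** Channels are smoothed with a mask-normalized Gaussian
filter: the kernel is renormalized over the region so that pixels outside
it carry zero weight and background never bleeds into the statistics;
`sigma = 0` is the identity. The default `sigma` is 2 px at the 512 px
working resolution — large enough to suppress single-pixel outliers (a
1% salt-and-pepper contamination moves the score by under 2 units),
small enough not to blur across a finger's width. Quartiles use
linear-interpolation (type 7) quantiles. The per-finger redness is

`redness = median(R) + (Q1(R) + Q3(R)) / 2`,

median plus midhinge of the smoothed red channel. This concrete formula is
this package's own instantiation: it uses exactly the stated ingredients
(median and quartiles of the red channel), is monotone in red intensity,
robust through both of its terms, and maps realistic dorsal skin tones
(red intensities ~150–205) onto scores of roughly 300–410, a dynamic
range comparable to what has been reported for this kind of index.
Weights, including an optional green/blue penalty (default weight 0 —
the green and blue channels are computed and reported but do not enter the
default score), live in `score_weights()`, and the formula version is
recorded in every output. Whether quartiles should be computed on raw or
smoothed values is ambiguous in prose descriptions of such scores;
smoothed was chosen because filtering is described as preceding the
statistics. Regions below 25 px are dropped with a warning as long as at
least three quarters of the scoring regions survive; otherwise the frame
errors out rather than returning a score built on too little evidence.

## Session model

The cold-challenge schedule is fixed: basal, then 0, 2, 4, 6, 8, 10
minutes after a 1-minute immersion at 15 °C — seven assessments. The
thermography aggregate is a mean of means (eight finger-region means,
then their mean), which differs from a pooled union mean whenever region
sizes differ; the package implements the two-stage form. "Returned to
baseline" is `value(10 min) >= value(basal)`, inclusive, so subjects who
overshoot their baseline count as returned.

## What the synthetic generator emulates

Hands are a filled palm ellipse plus five capsule-shaped digits, giving
pixel-exact masks, a per-digit partition and exact landmarks — the
property-based tests (digit disjointness, thumb exclusion, mirror
symmetry) rely on this exactness. Rewarming is mono-exponential towards a
subject-specific ceiling:

`value(t) = basal x (ceiling - (ceiling - (1 - drop)) exp(-rate t))`,

with i.i.d. Gaussian noise per finger and timepoint. Defaults (score
scale; warmer-season basal): RP basal 358 (SD 20), drop 0.10, rate
0.25/min, ceiling 1.015; HC basal 390 (SD 20), drop 0.07, rate 0.45/min,
ceiling 1.02; noise SD 6. Thermal scale: RP basal 28.5 °C, drop 0.18,
rate 0.25/min, ceiling 1.00; HC basal 32 °C, drop 0.20, rate 0.40/min,
ceiling 1.02; noise SD 0.5 °C. The colder season (September–December)
subtracts 25 score units and 2 °C from basal values. These constants are
design choices, not measurements: no quantitative attack or rewarming
kinetics are available for this exact protocol, so they were fixed once to
reproduce the qualitative structure a clinic cohort shows — patients
below controls at every timepoint, a marked seasonal shift, most subjects
recovering their photographic baseline by 10 minutes while fewer patients
recover their thermal baseline. Clinical covariates are sampled with
marginals resembling a secondary-RP-enriched clinic population, and their
additive effects on basal values (vasoactive therapy +14, ACA positivity
+20, male sex +13 score units, and analogous negative effects for late
capillaroscopic pattern and diffuse skin subset) are centred within each
group, so the expected group contrast stays exactly the difference of the
population defaults — this is what makes "recover the simulated group
effect" well defined.

The generator does **not** emulate photorealistic skin texture, skin-tone
diversity, shading, perspective, motion blur, or landmark-detector error.
Passing tests therefore demonstrate that the pipeline is correct and
internally consistent, not that it is robust to real-world imaging
conditions; those require clinical images that are not distributable.

## Statistical choices

- Group comparisons run Shapiro–Wilk on both samples and route to a
  two-tailed Student's t-test when neither rejects at 0.05, otherwise to a
  two-tailed Mann-Whitney U; the routing reason is recorded. Calibration
  under the null is verified by simulation (type-I error within
  0.03–0.07 over 2000 replicates).
- The 2x2 chi-square is Pearson's **without** continuity correction: on
  the published thermography return-to-baseline counts the uncorrected
  test reproduces the printed p-values (0.02 globally, 0.03 for the colder
  season) while the Yates-corrected version does not (~0.04). The choice
  is recorded in the report metadata.
- McNemar is the exact binomial test on discordant pairs — valid at
  cohort sizes of tens of subjects, where the asymptotic version is
  questionable.
- ROC analysis orients the score so that lower values indicate the patient
  class; AUC is the trapezoidal area (equal to the Mann-Whitney U
  statistic over n1 n2, verified as a property), the 95% CI is DeLong
  (bootstrap available), and the operating point maximizes Youden's J —
  a documented, configurable choice where no standard is stated.
- The multilinear regression screens predictors by variance inflation
  factor (threshold 10) before an OLS fit and refuses perfectly collinear
  designs, naming the offending columns.
- Multi-level covariates get thin wrappers: ANOVA with Bonferroni pairwise
  t-tests, or Kruskal-Wallis with Bonferroni-corrected pairwise Wilcoxon
  tests as the rank-based post hoc.
- The pooled group effect is the difference of per-subject session means
  (HC minus RP) with a Welch standard error. Its recovery target is the
  expected trajectory difference evaluated at the population-mean
  parameters; because the expectation of the mono-exponential is evaluated
  at the mean rate and ceiling rather than integrated over their
  distributions, the target carries a small Jensen-gap approximation,
  well inside the 2-SE acceptance band at the default cohort size.

## Numerical and degenerate-input conventions

Fixed seeds give bit-identical images, sessions, manifests and reports;
all generator randomness flows through an internal seed-scoping helper
that never disturbs the caller's RNG stream. Empty regions, missing
timepoints, one-class ROC inputs, zero-margin tables and constant
correlations raise classed errors rather than returning NaNs; two empty
masks compare as identical (IoU 1). Strata lacking a group, or with fewer
than 3 subjects per group, are skipped with a warning rather than
producing unstable comparisons.

## Problem sizes

The test suite and the acceptance script run at reduced scale chosen as a
deliberate design point: 160–192 px frames (the geometry is parameterised
at 512 px and rescales exactly), 150 synthetic hands (100 training / 50
held-out) for the segmentation validation analogue, 2000 replicates for
null calibration, and a 45 RP / 22 HC cohort — the size of the
motivating clinical study — for parameter recovery. Scores computed on
anisotropically resized two-hand frames carry a small constant negative
offset (edge pixels blend background into the lower quartile); it cancels
in all group and timepoint contrasts and is irrelevant to the arbitrary
unit scale, but absolute scores from differently sized frames should not
be mixed.

## Known limitations

Absolute score values are not comparable to any published clinical values:
the exact redness formula and unit scale of the original index are not
recoverable, so equality of absolute scores is explicitly out of scope —
orderings, calibration and discrimination are the validated surfaces. The
segmenters assume a dark, mostly uniform background; colour constancy
across phone models and calibration to absolute reflectance are not
attempted. Whether the per-timepoint score should average the eight digits
jointly (implemented) or per hand first is unresolved; with four digits
per hand the two differ only when regions are dropped asymmetrically.
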