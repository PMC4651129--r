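---
title: "Methods: automated tumour segmentation and ER scoring of TMA spots"
author: "tmascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tumour segmentation and ER scoring of TMA spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oestrogen-receptor (ER) status of a breast tumour is read from
immunohistochemically stained tissue: DAB (brown) marks ER in nuclei,
haematoxylin (blue) counterstains all nuclei. On tissue-microarray (TMA)
spots, scoring is restricted to tumour regions, which are conventionally
hand-drawn by a pathologist before a nuclear scoring algorithm runs. This
package implements the comparison study around replacing those hand-drawn
masks with automatically generated ones: segment tumour automatically,
quantify how the masks differ from manual ones at the pixel level, and —
the question that matters clinically — measure how much those differences
move the downstream Allred and Quickscore ER scores.

Because patient spot images cannot be redistributed, every stage is driven
by a seeded synthetic TMA-spot generator with exact ground truth. The
synthetic cohort defines the study conditions for all tests; what passing
tests do and do not show about real tissue is discussed at the end.

## The synthetic spot generator

`generate_spot()` renders a circular spot by a Beer–Lambert forward model.
Per pixel and channel, `value = round(bg_c * 10^-(h·v_h,c + d·v_d,c))`,
where `h`, `d` are per-pixel haematoxylin and DAB optical densities (OD)
and `v_h`, `v_d` are the unit Ruifrok–Johnston stain vectors. Because stain
contributions add in OD, the model is exactly the one inverted by colour
deconvolution, so forward/inverse round-trips are a numerical check of
both.

Composition of a spot:

* **Tumour regions.** `n_tumour_regions` anisotropic Gaussian bumps plus a
  smooth random modulation are thresholded at the quantile that makes the
  tumour area fraction equal `tumour_fraction` (default 0.30) of the
  in-spot pixels.
* **Compartments.** The non-tumour remainder is split into normal
  epithelium (~12% of the spot), lymphocyte fields (~6%) and stroma, again
  by smooth random fields. Mask labels remain {OUTSIDE, N, T}; compartments
  only drive nucleus placement.
* **Nuclei.** Placed per compartment by hard-core sampling (minimum
  centre spacing 2.3 nuclear radii) at densities of 1800 (tumour), 1500
  (normal epithelium), 4000 (lymphocyte) and 400 (stroma) per mm²,
  conventional orders of magnitude for breast tissue. Radii default to
  5/4/3/3 µm. Each nucleus is an ellipse with a flat-core radial profile
  (flat to 0.85 of the radius, cosine ramp to 1.1); overlapping nuclei sum
  in OD, keeping the forward model linear.
* **Tumour appearance.** A uniform 0.12 OD haematoxylin offset is added
  inside tumour regions, emulating the denser basophilic epithelial sheets
  of invasive carcinoma. This is what gives tumour/stroma a visible
  boundary — as in real H-DAB spots, where tumour is distinguishable by
  eye — and it is the signal the segmenter's colour features exploit. A
  low-amplitude smooth haematoxylin texture (0.05 OD, 8 µm correlation
  length) covers the stroma so texture features are non-degenerate.
* **Programmed ER score.** A fraction `programmed_percent_positive` of
  tumour nuclei (exact count, rounded) carries DAB at the peak OD of the
  programmed intensity bin. Peak ODs (0.35, 0.80, 1.45 for bins 1–3) are
  calibrated so the *detected per-nucleus mean* OD — the peak attenuated by
  the radial profile and the threshold-defined component extent — lands
  near the middle of the corresponding intensity bin (measured ≈0.27,
  0.53, 0.87). The attenuation is measurably nonlinear (brighter nuclei
  grow larger supra-threshold components with more fringe), which is why
  the peaks are not a constant multiple of the bin midpoints.

Defaults use a 600 px spot at 1 µm/px. Real spots are ~3000 px at ~0.25
µm/px; all geometry is parameterised in microns, so the defaults are a
configuration choice for fast experiments, not a constant of the method.
One integer seed drives a private RNG stream per spot; the caller's RNG
state is never touched, and identical configurations are bit-reproducible.

### Simulated annotators

`perturb_mask()` fabricates plausible annotator variation from ground
truth: `boundary_jitter` adds a smooth random field to the signed boundary
distance (boundary displacement bounded by the magnitude — thin, type-1
style disagreements); `region_resize` dilates or erodes whole tumour
components (type-2 style extent differences); `component_flip` adds or
deletes whole components (type-3 style presence/absence differences). In
`run_study()`, "annotator A" is ground truth with small jitter; "annotator
B" adds occasional resizes and flips, so synthetic inter-annotator
disagreement exhibits all three types.

## Automated segmentation

`compute_superpixels()` is a SLIC-style localized k-means in colour +
position space (implemented in C++ for speed), restricted to the spot
interior, with a connectivity pass that absorbs stray fragments. Seeds are
a fixed grid and the iteration count is fixed, so the result is
deterministic. With the default region size of 16 px, mean superpixel area
stays within a factor of two of 16² and, on synthetic spots, over 95% of
ground-truth tumour-boundary pixels lie within 2 px of a superpixel
boundary.

`extract_features()` summarises each superpixel by colour (mean/sd of RGB
and of deconvolved haematoxylin/DAB OD), texture (mean/sd of gradient
magnitude and Laplacian at 1 px and 3 px Gaussian scales), shape (area,
eccentricity, perimeter²/4πA compactness) and the mean of the adjacent
superpixels' colour/texture features over the region adjacency graph —
the "nearby superpixels" context. Training labels, when a reference mask
is supplied, are the majority T/N label of the superpixel's pixels; exact
ties go to N so tumour is never over-called. The same conservatism applies
at prediction: a superpixel is tumour only when the classifier's score
strictly exceeds 0.5.

The classifier is a random forest (200 trees): robust to mixed feature
scales, no tuning, seeded for reproducibility. `cross_validate()`
implements the spot-level k-fold design (default k = 8): folds are
contiguous blocks of a seeded shuffle, every spot is predicted exactly
once by a model whose training table contains no superpixel from that
spot.

An optional minimum-component-area filter is available for post-processing
predicted masks but is off by default; no other smoothing is applied.

## The three-type disagreement taxonomy

Two masks of the same spot are compared pixel-by-pixel over in-spot
pixels; the 2×2 contingency table over {T, N} summarises raw agreement.
Disagreement pixels are then classified, in order:

1. **Type 1** — the disagreement pixels *removed* by a morphological
   opening of the disagreement raster with a disc of diameter equal to the
   minimum epithelial cell diameter (default 8 µm at the image's pixel
   size): strips too thin to contain a cell, i.e. boundary-placement
   imprecision with no scoring consequence.
2. **Type 2** — a remaining disagreement pixel is T in exactly one mask;
   it is Type 2 iff its 8-connected T component in that mask shares at
   least one pixel with the other mask's T raster: a disagreement about
   the *extent* of a commonly identified tumour region.
3. **Type 3** — everything else: disagreement about whether a region is
   malignant at all.

Numerical choices worth stating explicitly:

* The disc is defined as the integer offsets with i² + j² ≤ (d/2)², and
  rasters are zero-padded before morphology so pixels beyond the raster
  are background. Both choices are part of the package's contract and are
  mirrored by the brute-force oracle in the test suite, which re-derives
  the classification from shifted-copy erosion/dilation and BFS flood
  fill on every random case.
* 8-connectivity everywhere: annotation strokes are thin and often only
  diagonally connected.
* Overlap for Type 2 means ≥ 1 shared pixel; no area threshold.
* Monotonicity caveat: enlarging the cell diameter enlarges the Type-1 set
  only when the larger digital disc is openable by the smaller one. That
  premise holds for Euclidean discs but fails for most digital diameter
  pairs, so rare single-pixel violations of monotonicity are possible and
  are a property of digital morphology, not a bug; the property test
  verifies the premise for the pair it asserts.

Per-spot type proportions are taken over that spot's disagreement pixels;
cohort summaries are unweighted mean ± sd over spots, excluding (and
counting) spots with no disagreement at all.

## Nuclear scoring

`colour_deconvolve()` converts RGB to OD (`-log10(I/bg)`, intensities
clamped to ≥ 1 count) and solves the 3×3 system for haematoxylin, DAB and
an orthogonal residual; negative projections are clipped to zero with the
clipped mass recorded. An 8-bit image cannot carry unlimited OD: at a
combined channel OD near 2 the transmitted signal is ~2 counts and
quantization alone contributes ~0.1 OD of error, so round-trip accuracy of
0.02 OD is only claimed (and tested) where per-channel intensity stays
comfortably above quantization — which covers everything the generator
renders.

`detect_nuclei()` thresholds the smoothed haematoxylin+DAB OD sum at 0.40
OD (diffuse tissue background peaks near 0.34; nuclear cores start near
0.7), splits touching blobs by a distance-transform watershed, and keeps
components whose centroid lies on a T pixel and whose area is within
12–300 µm². Only tumour regions are ever scored. Per-nucleus intensity
bins use half-open thresholds (0.15, 0.40, 0.70) OD — calibration
constants of this open scorer, not biological givens, and configurable.

`score_spot()` aggregates: percent positive is cell-count based; the spot
intensity score is the bin of the mean DAB OD over positive nuclei (a
configurable alternative takes the modal nucleus bin; how the commercial
scorer aggregates is proprietary, so both are documented interpretations).
Allred proportion bins (0, (0,1), [1,10), [10,33⅓), [33⅓,66⅔), ≥66⅔ → 0–5)
and Quickscore proportion bins ([0,5), [5,20), [20,40), [40,60), [60,80),
≥80 → 1–6) follow the standard published systems; totals add the intensity
score; ER positivity uses the exclusive cut-offs Allred > 2 (the 1% rule)
and Quickscore > 3. A spot with no detected nuclei scores zero throughout
(Quickscore proportion 1) with a warning.

## Agreement statistics

Observed agreement is diagonal mass. Cohen's kappa is `(po − pe)/(1 − pe)`
with `pe` from marginal products. Ordinal score agreement uses two-rater
weighted kappa with quadratic (Fleiss–Cohen) disagreement weights
`((i−j)/(k−1))²` — the standard reading of a "kappa-squared" statistic —
with linear weights available. Confusions are always built over the full
category range (intensity 0–3, Allred totals 0–8, Quickscore totals 1–9)
so chance expectations are well-defined across cohorts even when
categories are unobserved. Degenerate cases (both sources constant) return
a flagged `NA` rather than an error so cohort tables stay rectangular.

A note on the pixel-level statistics: the headline pixel "kappa" values
quoted for this kind of study equal the *diagonal sums* of the normalized
contingency tables (observed agreement). Chance-corrected Cohen's kappa on
the same tables is lower (≈0.787 for a two-pathologist table with 0.908
observed agreement). The package computes both and takes no position on
which was intended; the acceptance outputs report them side by side.

Bland–Altman analysis of percent positive reports the mean difference
(bias) and bias ± 1.96 sd limits of agreement, with plot-ready
coordinates. `score_histograms()` tabulates Allred and Quickscore totals
per mask source.

## The end-to-end study

`run_study()` chains the stages: generate a cohort (programmed ER profiles
cycle through a list spanning negative to strongly positive), derive
annotator A and B masks, cross-validate a segmenter per annotator, build
pooled contingency tables and per-spot disagreement summaries for the five
source pairs, score every spot under every mask source (ground truth
included), and compute weighted-kappa matrices, ER-status concordance and
Bland–Altman results. Everything derives from one seed; report CSVs are
byte-identical across reruns.

Problem sizes used by the packaged checks: the scoring round-trip uses 20
spots of 600 px spanning percent-positive {0, 0.5, 5, 25, 50, 90} and
intensity bins 0–3; the segmentation-recovery check cross-validates 16 of
those spots with k = 8; the acceptance script runs a 16-spot study at
600 px. These sizes were chosen as the smallest cohorts that exercise
every score category and fold structure.

## What the synthetic study does and does not show

The generator reproduces the *structure* of the real study — circular
spots, compartmentalised tissue, nuclear H-DAB staining rendered through
the same physics the scorer inverts, annotator variation in all three
disagreement types — with exactly known truth. It does not attempt
photorealism: no tissue folds, out-of-focus blur, scanner compression,
stain batch variation, overlapping nuclear clumps beyond OD summation, or
ER-negative tumour admixed with ER-negative normal epithelium of identical
appearance (a known hard case for the real segmenter). Synthetic
tumour/stroma contrast is cleaner than histology, so segmentation and
score-agreement figures on synthetic cohorts sit near the top of the
ranges reported on patient material and should be read as verifying the
pipeline's correctness and internal consistency, not as clinical
performance estimates. Reproducing the patient-cohort tables is
explicitly out of scope: those numbers depend on the 32 unavailable
patient spots.

## Known limitations

* Digital-disc monotonicity caveat for the Type-1 rule (above).
* 8-bit OD quantization bounds deconvolution accuracy at high OD (above).
* The spot intensity aggregation and positivity threshold of the
  commercial scorer are unknown; both are exposed as configuration with
  documented defaults.
* Multi-rater (> 2) agreement and kappa confidence intervals are out of
  scope.
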