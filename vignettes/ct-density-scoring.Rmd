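---
title: "Density-based CT scoring of structural lung disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based CT scoring of structural lung disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdens)
```

## The measurement problem

In bronchiectatic lung disease — primary ciliary dyskinesia (PCD) is the
motivating case — the structural abnormalities visible on chest CT
(bronchial wall thickening, mucus plugging, tree-in-bud, consolidation,
atelectasis) are all *denser* than aerated parenchyma. Healthy inspiratory
lung attenuates around −850 HU with a sharp, right-skewed density
histogram; disease adds mass to the right (dense) side of that histogram.
`lungdens` turns this into a number: the **CT-density score**, the
percentage of lung voxels with attenuation at or above a threshold
(inclusive: a voxel exactly at the threshold counts). A score of 10 means
10% of the lung is at least as dense as the threshold.

The pipeline is: isolate the lungs, characterize the density histogram
(MLD, mode, SD, skewness, kurtosis), resolve a threshold — fixed in HU or
*adapted* to the patient's own histogram — and report the percentage at or
above it, for the whole lung and for upper/lower regions.

## Why adapted thresholds

Lung attenuation depends on the inspiratory level, the kilovoltage and
patient positioning, not only on disease. Expiration shifts the whole
histogram toward higher densities and flattens it (higher MLD and mode,
higher SD). A fixed threshold confounds these global changes with disease
burden. An adapted threshold of the form

$$T = B + \delta + k\,\mathrm{SD}, \qquad B \in \{\mathrm{MLD},
\mathrm{Mode}\}$$

moves with the histogram. Formally, for an affine change of all lung
voxels $v \mapsto a\,v + b$ ($a>0$) — our model of the inspiration level —
MLD and Mode map to $a\,\mathrm{MLD}+b$ and $a\,\mathrm{Mode}+b$ and SD to
$a\,\mathrm{SD}$, so a threshold $B + k\,\mathrm{SD}$ maps to exactly the
affine image of the original threshold and the score is unchanged. The
offset form $B + \delta$ is invariant under shifts ($a = 1$) but not under
spread changes, since a fixed HU offset cannot scale; the test suite
asserts exactly these two regimes. Fixed thresholds are invariant under
neither.

The default suite evaluates twelve rules per scan: fixed
{−300, −400, −500, −600} HU and adapted {MLD+2SD, MLD+1SD, Mode+500,
Mode+400, Mode+300, Mode+3SD, Mode+2SD, Mode+1SD}. The four fixed values
are the union of the two fixed sets that appear in the literature on this
score (−300/−400/−500 and −400/−500/−600); keeping all four costs nothing
and sidesteps the ambiguity. `MLD+1SD` is flagged `recommended`: it is the
best-performing rule in the validation literature and needs only the two
quantities every densitometry tool prints.

## Histogram characteristics

* **MLD** — arithmetic mean of the masked HU values.
* **SD** — *population* (divide-by-n) standard deviation. Lung regions
  hold $10^5$–$10^7$ voxels, so the $n$ vs $n-1$ distinction is far below
  measurement noise, and population moments match closed-form test
  oracles exactly.
* **Skewness / kurtosis** — third and fourth standardized central
  moments; kurtosis defaults to the *excess* convention (Gaussian = 0)
  with the non-excess convention selectable, because the convention used
  by commercial densitometry software is generally not documented. Both
  conventions necessarily order patients identically. On a constant
  region (SD = 0) both are reported as `NA` with a `moments_defined =
  FALSE` flag — never silently zero.
* **Mode** — the attenuation of the histogram peak. Two estimators are
  provided. The default locates the argmax on *standardized* values
  $(v-\mathrm{MLD})/\mathrm{SD}$ with a fixed bin width of 1/60 in SD
  units (≈ 1 HU for the typical inspiratory parenchymal SD of 60 HU) and
  maps it back to HU. This construction commutes exactly with affine HU
  changes, which makes Mode-anchored adapted thresholds genuinely
  inspiration-invariant; an absolute-binning argmax cannot have this
  property (the binning does not commute with scaling, and on a flat
  Gaussian peak the argmax wanders several HU between binnings).
  `mode_method = "binned"` gives the classical argmax over 1-HU bins
  aligned to integer multiples of the width. Ties break toward the lowest
  HU in both, so the mode is deterministic on near-integer CT data.

Moments are always computed from the raw masked voxel values, never from
binned counts; the histogram object exists for reporting and plotting.
Histogram bins are half-open $[lo, hi)$ and integer-aligned, so a value
lying exactly on an interior edge belongs to the right-hand bin.

## Lung segmentation

The reference workflow used commercial segmentation software; `lungdens`
replaces it with a transparent rule-based pipeline chosen for
reproducibility without training data:

1. threshold at −320 HU (aerated lung vs everything else);
2. 3-D 6-connected components (compiled code);
3. discard components touching the volume border — that is the outside
   air, and any airway column reaching the top of the stack;
4. optionally remove trachea-like components: narrow (mean per-slice
   cross-section ≤ 300 mm²), near the midsagittal plane, present in the
   cranial third;
5. keep up to the two largest components of at least 200 mL;
6. fill holes per axial slice — this reinstates vessels and dense lesions
   that the air threshold excluded, which is essential: they are exactly
   the high-attenuating voxels the score counts;
7. morphological closing (ball, default radius 2 mm);
8. label left/right by component centroid; a fused single component is
   split at the midsagittal plane of the body bounding box.

Defaults (−320 HU, 200 mL, 2 mm) are conventional values for adult chest
CT; all are parameters of `seg_params()`. No resampling is performed;
slice thickness is whatever the volume carries. Whether large-airway
lumen voxels belonged to the "lung" histogram in the commercial tool is
unknowable; the default here excludes the trachea and main bronchi only.

The upper/lower partition defaults to `axial_fraction = 0.5`: each lung is
cut at the axial plane that places half of its voxels cranially (the cut
plane goes to the upper block, so the split is exact to within one slice).
The faithful alternative, when a lobe map exists, groups lobes as upper =
{right upper lobe, upper part of the left upper lobe} and lower = {middle
lobe, lingula, lower lobes}. Manual fissure contouring is out of scope.

For regional scores the adapted threshold is resolved **once from
whole-lung features** and shared by the upper and lower regions, so an
upper–lower difference reflects where the dense voxels are, not a
difference between regional histogram shapes. This is a deliberate
design choice (`resolve_from = "region"` reverts it). A corollary used as
a test invariant: the whole-lung score is exactly the voxel-count-weighted
mean of the regional scores.

## The statistical battery

* `spearman_cor()` — R is the Pearson correlation of midranks; two-sided
  p from the t approximation at cohort sizes, or the exact permutation
  distribution (all distinct permutations of one rank vector) for
  n ≤ 10, which the oracle tests enumerate independently. Bands follow
  the conventional cutpoints |R| < 0.4 absent-to-weak, < 0.6 moderate,
  < 0.8 good, ≥ 0.8 strong (the published cutpoints leave (0.79, 0.8)
  unassigned; we close the gap with right-open intervals).
* `wilcoxon_paired()` — signed-rank V on nonzero differences with
  midranks. For n ≤ 25 the p-value is exact even under ties: the
  conditional sign-flip distribution of V given the observed |d| ranks,
  built by convolution over doubled ranks (identical to the classical
  signed-rank distribution when untied, and to full 2^n enumeration
  always). Larger n uses the tie-corrected normal approximation without
  continuity correction.
* `icc_agreement()` — ICC(2,1), two-way random effects, absolute
  agreement, single rater, from the ANOVA mean squares. This form fits
  the design it is used for (two fixed raters scoring the same scans);
  when the whole table has no variance the ICC is flagged undefined
  rather than forced to 1.
* `bland_altman()` — bias = mean(a−b), limits of agreement bias ±
  1.96·SD with the sample (n−1) SD, the conventional choice.
* `bhalla_total()` — the visual-score comparator. The nine category
  definitions live in configuration (`bhalla_rubric()`), with the default
  maxima (3,3,3,3,3,3,3,2,2). The total is the plain sum of subscores, so
  it is 0 for a normal scan and monotone non-decreasing in every
  category; the historical "25 minus sum" presentation is a fixed affine
  relabeling of the same quantity and can be applied downstream if
  preferred.

## The phantom generator

No public CT data accompany this method, so validation is built on
synthetic chest phantoms that reproduce the *statistical* structure the
score relies on, with exact ground truth:

* a soft-tissue body ellipsoid (+40 HU) in outside air (−1000 HU);
* two lung ellipsoids whose parenchyma is Gaussian −850 ± 60 HU
  (inspiratory adult lung);
* vessel-like random tubes (radius 1–3 voxels, 3% of lung volume by
  default) at +30 ± 20 HU — these create the bright right tail (positive
  skew, high kurtosis) that real lung histograms show;
* disease as spherical lesion blobs (radius 2–5 voxels) at −150 ± 100 HU
  *replacing* parenchymal voxels, so lung volume is conserved and the
  lesion fraction `f` is exact by construction (the last blob is trimmed
  to the exact voxel target; truth metadata records realized per-region
  fractions that match the voxel map exactly);
* optional spatial bias of lesions toward the lower lungs, an optional
  trachea-like air column, optional additive scanner noise, and the
  inspiration transform `v -> MLD + a (v − MLD) + shift` on lung voxels.

Defaults the method literature does not pin down were chosen once, on
radiological plausibility, and not revisited: 96³ voxels at 3 mm (a
~29 cm field of view that keeps a phantom under a second to generate),
lesion blob radii 2–5 voxels (≈ 6–15 mm, bronchiectatic cluster scale),
vessel tube radii 1–3 voxels, healthy default `f = 0`, unbiased default
lesion placement. All randomness flows from the single spec seed; the
same spec is bitwise reproducible.

`generate_cohort()` ties burden to surrogate spirometry:
`FEV1 = 100 − 300 f + N(0, 5)` %predicted (independently for FVC),
clamped to (0, 130]. With `f ∈ [0, 0.15]` the simulated signal-to-noise
gives a rank correlation near −0.9 between the MLD+1SD score and
surrogate FEV1 — comfortably inside the "at least good negative
correlation" recovery property the tests assert. What the phantoms do
**not** model: airway trees and fissures, textured parenchyma,
reconstruction-kernel noise correlation, gravity-dependent density
gradients. Passing the suite therefore shows the *method* behaves as
specified under its own assumptions, not that any particular clinical
correlation will be reproduced on real scans.

## Numerical and degenerate-input policy

* HU values below −1024 are retained, never clipped; construction flags
  their count.
* Empty regions, all-air volumes (no body), and soft-tissue-only volumes
  (no lung candidate ≥ 200 mL) are typed errors, not empty results.
* Scores are computed from raw voxel values (no binning at the
  threshold); comparisons are inclusive ≥.
* Adapted thresholds on a zero-SD region are an error (`MLD+0·SD` would
  silently degenerate otherwise).
* Mask/volume binding checks shape and spacing (tolerance 1e-3 mm).
* Outputs round scores to 2 decimals only at the CSV/JSON boundary; all
  in-memory comparisons run at full precision.

## Problem sizes used by the validation suite

The test suite generates phantoms at 48³–64³ voxels for unit-level
properties, a 20-phantom sweep at 64³ for the histogram-shape direction
property, and a 30-phantom cohort at the full 96³ default for the
correlation-recovery property; the Monte-Carlo oracles use 10⁶ draws.
These sizes were chosen so the whole suite completes in well under a
minute on one core while keeping every Monte-Carlo tolerance at ≥ 4
standard errors.

## Known limitations

* Pulmonary vessels are counted as high-attenuating volume; the score is
  disease + vasculature. Vessel exclusion would need vessel
  segmentation, deliberately out of scope.
* The rule-based segmentation assumes a whole-thorax axial acquisition
  with air surrounding the body; it is not a clinical segmentation tool.
* The DICOM reader supports the uncompressed little-endian transfer
  syntaxes that CT scanners write; compressed or big-endian series must
  be converted upstream.
* Longitudinal change scores and multivariable modelling are out of
  scope.
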