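---
title: "Methods: early NAC-response prediction from longitudinal PET/MRI phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early NAC-response prediction from longitudinal PET/MRI phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In advanced breast cancer, neoadjuvant chemotherapy (NAC) is given before
surgery, and the pathological response — graded on the five-level
Miller–Payne scale after surgery, with grades 4–5 counted as response — is
only known months after treatment starts. Early interim imaging (after the
first NAC cycle) offers a chance to predict that response while therapy can
still be changed. Two families of predictors compete:

* **Conventional scalar parameters.** From FDG-PET: the maximum standardized
  uptake value (SUVmax), the metabolic tumour volume (MTV: the volume of
  lesion voxels with SUV at or above 2.5), and total lesion glycolysis
  (TLG = MTV × mean SUV of those voxels). From diffusion-weighted MRI: the
  mean apparent diffusion coefficient (ADC) inside a circular tumour ROI,
  with the ADC map computed from a two-point acquisition at b = 0 and
  b = 800 s/mm² as ADC = ln(S₀/S₈₀₀)/800. Each parameter is measured at
  baseline (index 0) and interim (index 1), and summarized as a percent
  change, e.g. ΔSUV(%) = (SUV1 − SUV0) × 100 / SUV0.
* **A small image classifier.** A compact AlexNet-style convolutional
  network applied to 64×64 crops of the lesion's largest cross-section,
  one crop per patient per modality/timepoint (PET0, PET1, MRI0, MRI1).

Clinical cohorts of this kind are small and heavily imbalanced (on the order
of 6 responders against 50 non-responders), which forces two methodological
devices this package implements faithfully: rotation augmentation of the
minority class (each responder image rotated seven times in 45° increments,
turning 6 responders into 48 responder images in a 98-image set) and k-fold
cross-validation inside the 80/20 train/test split.

Because cohorts like this are private, the package ships a **synthetic
phantom generator** with known ground truth, so that every downstream stage
is testable end to end, and so that claims about the analysis code are
checked against exhaustively enumerable oracles rather than against
irreproducible clinical numbers.

## The phantom cohort generator

`cohort_config()` / `generate_cohort()` simulate each patient as an
ellipsoidal tumour in a 3-D voxel grid with physical spacing:

* **PET.** In-tumour SUV follows a quadratic profile that peaks at a drawn
  SUVmax in the center voxel and falls to 40% of the peak at the rim; this
  keeps the peak unambiguous while giving the threshold-based MTV a
  non-trivial boundary. Background tissue sits at a low constant SUV.
  Noise is multiplicative Gaussian (relative sd `noise_sigma`), floored at 0.
* **DWI.** The tumour and background are piecewise-constant ADC regions; the
  b = 0 volume is a constant signal `s0_level` and the b = 800 volume follows
  the monoexponential decay `s0 · exp(−b·ADC)`. Noise is Rician with scale
  `noise_sigma · s0_level`, the standard magnitude-MR model. With zero noise
  the pair inverts exactly: `adc_map()` reproduces the ground-truth field to
  ≤ 1e−9 relative error (asserted in the tests).
* **Longitudinal effects.** Responders draw a large metabolic decline and an
  ADC rise; non-responders draw small changes. Interim tumours shrink their
  semi-axes by the cube root of the drawn volume change and scale their peak
  SUV by the drawn ΔSUV, coupling volumetric and intensity effects. Default
  effect sizes (ΔSUV −70 ± 15% vs −20 ± 15%; ΔADC +40 ± 15% vs +5 ± 10%;
  ΔMTV −90 ± 8% vs −30 ± 20%) were chosen once so the class distributions
  straddle the cutoffs typical of early-response studies (≈ −56% for ΔSUV,
  ≈ +25% for ΔADC); they are not claimed to match any particular cohort.
* **Truncation is truth.** Draws are truncated at small positive floors
  (baseline SUVmax ≥ 3, interim peak ≥ background + 0.1, ΔMTV ≥ −99.9%,
  ΔADC ≥ −90%) so every rendered intensity stays positive. The *applied*
  value is recorded as the patient's ground truth, which is why the
  effect-size recovery test can demand ≤ 0.5% absolute agreement on
  noiseless phantoms rather than a loose statistical bound.
* **Labels and subtypes.** Miller–Payne grades are drawn uniformly from
  {4,5} for responders and {1,2,3} for non-responders — so grade ≥ 4 iff
  responder by construction — and ER/PR/HER2 flags are independent
  Bernoulli draws with prevalences defaulting to the marginal proportions
  of a 56-patient advanced-breast-cancer cohort (45% / 58% / 38%). The
  flags exist purely to exercise subgroup filtering.
* **Optional texture.** With `texture_flag = TRUE`, responder tumours (both
  timepoints, PET and ADC) receive multiplicative voxel-scale speckle of
  amplitude `texture_amp`. This plants a class signal that survives the
  per-crop min–max normalization but is invisible to SUVmax-style scalar
  summaries — the device used to test that the CNN can outperform the
  conventional parameters when the discriminative information is textural.
* **Reproducibility.** One top-level seed; each patient consumes an
  independent substream indexed by patient counter, so enlarging a cohort
  never reshuffles the patients already generated. Identical configs are
  bit-identical.

What the phantom deliberately does **not** emulate: scanner point-spread
functions and partial-volume effects, anatomical background classes, DICOM
metadata, co-registration error between PET and MR, multi-focal disease, and
intra-tumour gradients beyond the fixed quadratic profile. Tests passing on
phantoms therefore validate the *analysis machinery* — segmentation
arithmetic, formulas, splits, training bookkeeping — not clinical
performance.

## Conventional quantification

* **Voxel membership is by center.** A voxel belongs to an ellipsoid VOI or
  circular ROI iff its center satisfies the region inequality (in mm, so
  anisotropic spacing is handled). This is unambiguous and lets every
  measurement be checked against a brute-force voxel scan; the test suite
  asserts exact agreement on hundreds of random volumes.
* **The MTV threshold (default SUV 2.5) is inclusive** (≥ 2.5). The
  convention is pinned by a test so the behaviour cannot drift.
* **ADC units.** Volumes store raw mm²/s; `ParameterRecord`s report
  10⁻³ mm²/s. ADC voxels whose source signal falls below `signal_floor` are
  invalid (`NA`) and excluded from ROI means; noise-induced negative ADCs
  clamp to 0.
* **Percent changes** are undefined at baseline 0; such Δ values are `NA`
  and the patient is dropped from that parameter's ROC only (per-parameter
  n is reported). This happens naturally for ΔMTV/ΔTLG when the baseline
  lesion is entirely sub-threshold.
* **Placement.** In the pipeline, VOIs/ROIs are placed from generator ground
  truth (center, semi-axes with a 30% margin; ROI radius 60% of the
  in-plane semi-axis, floored at one voxel). Manual placement is out of
  scope. The "largest cross-section" slice is the axial slice with the most
  in-region voxels, ties broken toward the lowest index.

## ROC analysis

`roc_analysis()` computes the AUC through the Mann–Whitney identity with
ties counted ½, orients the score so AUC ≥ 0.5 (recording the direction),
uses the DeLong placement-variance for the 95% CI and for a normal-theory
p-value against AUC = 0.5, and picks the operating point maximizing
Youden's J over midpoints between adjacent distinct scores. Tie-breaks are
deterministic: higher sensitivity first, then the threshold farther from the
score median, then the lower threshold. The CI method is a deliberate,
recorded choice — small-sample clinical software varies here, and no exact
numeric agreement with any particular tool is claimed; the AUC itself is
tested against an exhaustive pair-ordering oracle on all small instances.

`rank_compare()` (used to compare fold metrics before vs after
augmentation) is a two-sided Mann–Whitney U test: exhaustive enumeration
over all group assignments when both samples have ≤ 8 values (exact even
under ties), otherwise the tie-corrected normal approximation without
continuity correction.

## The CNN

Architecture (fixed by design): two 5×5 convolution layers with 32 filters
each (stride 1, zero padding, ReLU), each followed by 2×2 max-pooling; then
two fully-connected layers (ReLU hidden layer, 2-unit softmax output);
softmax cross-entropy loss; Adam. Dropout acts on the inputs of both
fully-connected layers — "dropout in the first and second fully-connected
layers" cannot sensibly mean dropping the 2-unit softmax output itself.
Unspecified hyperparameters are explicit, overridable defaults:
hidden width 256, dropout 0.5, learning rate 1e−4, batch size 16,
100 epochs, no early stopping.

The implementation is self-contained: the convolution forward/backward
passes are im2col/col2im kernels in compiled code (RcppArmadillo), everything
else is vectorized R. Analytic gradients are verified against numerical
differentiation in the tests.

Data handling decisions:

* **Crops.** One 64×64 crop per patient per modality/timepoint, taken at the
  lesion's largest cross-section: a square window of the tight bounding box
  side + 20% margin, bilinearly resampled and min–max normalized to [0, 1]
  per image. The normalization removes absolute SUV/ADC scale so the network
  must use morphology and texture rather than an intensity shortcut.
* **Rotations** happen after resize/normalization, about the image center,
  with zero fill outside the support. Multiples of 90° are exact index
  permutations — the 180° rotation equals the double axis flip bit for bit —
  and odd multiples of 45° use the same bilinear sampler as cropping.
  Augmentation applies to responder images only; the originals are not
  duplicated in the augmented output (6 originals → 42 rotated copies).
* **Patient-level splitting.** The 80/20 split and the k-fold assignment are
  stratified by class and operate on patients, so an augmented copy can
  never land on the other side of a split from its source image. Whether
  the original study split at image level is unknowable from its text;
  patient-level is the conservative choice, and the no-leakage property is
  asserted exhaustively in the tests. Reported test metrics come from the
  held-out 20% using the mean responder probability of the k fold models;
  validation metrics are reported per fold with fold means and medians.
* **Determinism.** Weight init, shuffling, dropout and fold/split
  assignments all derive from explicit seeds; two runs of the same config
  agree bit for bit (asserted on the full pipeline report).

## Problem sizes

The package's own simulations are run at desk scale, stated here as the
package's choices: test cohorts use 24³–32³ grids at 2 mm spacing with
tumour semi-axes of 5–10 mm, and CNN checks use 8–16 filters, hidden width
16–64 and 2–10 epochs; the acceptance script runs the full pipeline at a
48³ grid, 8–16 mm tumours, 32 filters, hidden width 64 and 8 epochs with a
raised learning rate (1e−3) to converge within that budget. These sizes
preserve every bookkeeping identity (98/48 augmented counts, fold
partitions, report completeness) and the qualitative orderings of interest;
they do not reproduce clinical AUC magnitudes, which depend on a private
cohort and are not targets of this artifact.

## Known limitations

* The phantom's two-class effect model is Gaussian and unimodal; real
  response distributions are messier, and the generator makes no attempt to
  model confounders (age, subtype-dependent effects, scanner drift).
* Subtype flags are independent of response, so subgroup analyses exercise
  the plumbing but contain no planted subgroup effect.
* Multi-focal lesions are not modelled, and no merging rule is implemented
  for them; the single-lesion assumption is explicit.
* The AUC p-value and CI are asymptotic (DeLong + normal); with 6 positives
  they are rough, exactly as they are in the clinical setting this mirrors.
* `evaluate_ensemble()` reports the orientation-corrected AUC (≥ 0.5), so an
  anti-learning classifier is reported by its flipped discrimination with
  the direction flag set — consistent with how the conventional parameters
  are scored.
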