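---
title: "Methods: slide-level NEN grading from density maps and Ki-67 quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slide-level NEN grading from density maps and Ki-67 quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nengrader)
```

Neuroendocrine neoplasms (NENs) are graded G1–G3 from two proliferation
measurements: the mitotic count in the most active 2 mm² of an H&E slide,
and the Ki-67 index (percentage of tumor cells staining positive for the
Ki-67 antigen) in the most proliferative region of an immunohistochemistry
slide. `nengrader` implements both measurements from whole-slide-image
derivatives, turns them into slide-level feature vectors, grades slides by
rule or by learned classifier, and evaluates how well the resulting grades
stratify survival. Seeded generators produce synthetic data with exact
ground truth so every stage can be tested as a parameter-recovery problem.

## 1. Classical Ki-67 quantification

`ki67_patch_index()` runs a fully classical chain on one RGB
immunohistochemistry patch:

1. **Optical density and colour deconvolution.** Each pixel is converted to
   optical density, `OD = -log10(I / I0)`, and unmixed into hematoxylin
   (all nuclei) and DAB (Ki-67-positive nuclei) contributions with the
   Ruifrok–Johnston H-DAB stain matrix (`hdab_stain_matrix()`,
   unit-normalized rows). `separate_stains()` returns the two
   concentration planes.
2. **Otsu thresholding.** `binarize_channel()` thresholds each plane with
   Otsu's method. A plane whose amplitude is below 0.05 OD is treated as
   empty: Otsu always returns *some* split, and on a signal-free plane that
   split is sensor noise. The 0.05 guard is well below any real stain
   signal (nuclei render at 0.5–1.0 OD) and well above shot noise.
3. **Morphological expansion.** The binary masks are dilated with a
   5-pixel-radius Euclidean disk (`expand_mask()`), merging
   fragmented nuclear staining before counting.
4. **Circular Hough counting.** `detect_circles()` counts nuclei in each
   mask with a gradient-voting circular Hough transform (radii 8–40 px,
   minimum centre distance 16 px, accumulator threshold 30). The index is
   `100 * n_positive / n_total`, and a patch qualifies only if at least
   500 cells were found (clinical practice assesses 500–2000 cells).

The Hough transform is implemented in C++ (`src/hough.cpp`) because no
installed R package provides one. Its parameters were frozen once against
the synthetic patch generator (nucleus radii 9–15 px at the default
resolution, well inside the 8–40 search band) and are exposed in
`ki67_config()`; they are detector settings, not tuned quantities. Default
patches are 1536 px square — large enough at 0.2525 µm/px to hold the
500-cell minimum.

Numerical conventions used throughout: histogram binning rounds half-up
(`floor(x + 0.5)`) so bin edges are deterministic across platforms, and
all image coordinates are 0-based pixel positions with `x` along columns.

## 2. Mitotic density maps and hotspots

Mitotic-figure detections arrive as a table of level-0 pixel coordinates
with confidence scores (`read_detections()`). `quantize_detections()` bins
score-thresholded detections into a patch grid (512-px patches by
default), and `sliding_sum()` convolves the count grid with a square
window covering 2 mm²: `window_patches_for_area(2, mpp = 0.2525,
patch_px = 512)` gives an 11-patch side. The window sum is computed with a
summed-area table in C++ and is checked in the tests against an
independent double-loop oracle. `hotspot()` returns the maximal window —
the clinically reported mitotic count. Ki-67 slides get the analogous
per-patch map of qualifying patch indices (`ki67_index_map()`).

## 3. Slide features and grading

`build_histogram()` reduces a density map to a normalized histogram:
49 bins (0–48, values clipped at 48) for mitotic maps, 101 bins (0–100)
for Ki-67 maps. The clip keeps the support fixed while preserving the
"very active" tail mass. `concat_features()` joins both histograms into a
150-dimensional vector for a single classifier over both stains.

Grading has two routes:

- **Rules.** `who_grade_mitotic()` (<2 / 2–20 / >20 per 2 mm²) and
  `who_grade_ki67()` (<3% / 3–20% / >20%), both inclusive at the band
  edges; `combined_grade()` takes the maximum, as WHO reporting requires.
  `naive_combination_1()` and `naive_combination_2()` combine a learned
  H&E grade with the Ki-67 measurement or grade the same way.
- **Learned.** `train_histogram_classifier()` fits either a single-hidden-
  layer MLP (`nnet::nnet`, softmax output) or multinomial logistic
  regression (`nnet::multinom`) on histogram features, with
  inverse-frequency class weights. The MLP default is 64 hidden units;
  `nnet`'s BFGS optimizer scales poorly in the weight count, so for large
  feature sets a narrower layer (8–16 units) trains orders of magnitude
  faster and, on the synthetic cohorts, loses no accuracy — the test suite
  exercises `hidden_units = 8`. `nnet` exposes no per-epoch callback, so
  regularisation is L2 weight decay (default 5e-4) with a fixed iteration
  cap rather than early stopping on a validation metric.

`run_cv()` performs grade-stratified k-fold cross-validation (default
k = 3) with each held-out fold split into test and validation roles, and
reports per-fold and mean balanced accuracy (the unweighted mean of
per-class recalls, robust to the heavy G1 skew of NEN cohorts).

## 4. Survival evaluation

`km_estimate()` wraps `survival::survfit` (log-log confidence intervals),
`median_survival()` reads the first time the curve drops to 0.5 or below,
and `logrank()` wraps `survival::survdiff`. `harrell_c_index()` is
hand-written to the standard admissible-pair definition (the
shorter-time member of a pair must have an observed event; tied times are
excluded; tied risks score 0.5) and is verified in the tests against both
an O(n²) brute force and `survival::concordance`.

## 5. Synthetic data: scope and limits

Three seeded generators provide ground truth. All of them save and
restore the RNG state, so they compose without disturbing a session.

- `gen_ihc_patch()` renders nuclei as Beer–Lambert-composited disks
  (anti-aliased edges) on a jittered lattice that guarantees a minimum
  separation of 44 px; positive counts are exact
  (`round(positive_fraction * n_cells)`). Infeasible packings fail with an
  error rather than degrading. Limits: no overlapping or clumped nuclei,
  no tissue texture, uniform stain intensity — it validates the counting
  chain, not segmentation robustness.
- `gen_detection_field()` plants a circular Poisson hotspot
  (rate 5 per patch, radius 3 patches) on a low-rate background (0.05)
  and records the brute-force maximal 11×11 window as truth.
- `gen_cohort()` simulates a patient cohort under fixed study conditions:
  grade mix (0.59, 0.30, 0.11) echoing the G1-heavy composition of real
  NEN series; exponential survival with per-grade scales (8, 5, 1.5)
  years and ~30% independent exponential censoring; grade-conditional
  hotspot mitotic counts and Ki-67 indices. In the `"separated"` variant
  both measurements are drawn inside their WHO bands, so rule-based
  recovery is perfect by construction; in the `"overlapping"` variant the
  mitotic supports overlap across grades while Ki-67 remains informative,
  which is the regime where concatenated features should beat H&E-only
  features. These conditions were fixed when the generator was designed
  and are not tuned to any test outcome.

Problem sizes used in the test suite: 1536-px patches with 700 nuclei,
40×40 patch grids, cohorts of 80–400 patients, 3-fold cross-validation at
n = 300.

## 6. Limitations

- No WSI tiling or DICOM support; the package starts from patches,
  detection tables, and masks.
- Mitotic-figure *detection* itself (the object-detection model) is out
  of scope; detections are inputs.
- The classical Ki-67 chain assumes H-DAB staining and the default
  resolution; other chromogens need a different stain matrix.
- Synthetic cohorts are a recovery benchmark, not a clinical simulation;
  headline accuracies on them (near 1.0) say the machinery is correct,
  not that real-slide grading is solved.
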