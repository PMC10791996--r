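---
title: "Estimating winter wheat LAI from UAV imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating winter wheat LAI from UAV imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatlai)
```

## The estimation problem

Leaf area index (LAI, one-sided leaf area per unit ground area, m²/m²) at
the jointing stage is the key state variable for winter wheat topdressing
decisions. `wheatlai` implements a pixel-based empirical pipeline that
estimates LAI from a four-band UAV reflectance orthomosaic (green 550 nm,
red 660 nm, red edge 735 nm, NIR 790 nm; 0.1 m grid) and a pair of digital
surface models, by fusing three feature families:

* **Vegetation indices (VI)** — 17 closed-form band combinations (NDVI,
  EVI2, MSAVI, CLre, MTCI, ...), evaluated per pixel or on band values
  extracted at sample points.
* **Texture indices (TI)** — gray level co-occurrence matrix (GLCM)
  statistics (8 per band, 32 layers) expanded into pairwise normalized
  difference, difference and ratio combinations (NDTI/DTI/RTI, 1984
  candidates).
* **Plant height (PH)** — a canopy height model from DSM differencing,
  `PH = (DSM1 − DSM0) · 100` cm, clipped at zero.

Candidate features are screened by Pearson correlation with measured LAI
(|r| ≥ 0.80 after two-decimal rounding, p < 0.01), samples are partitioned
70/30 into calibration and validation sets with SPXY (Kennard–Stone
selection on the joint feature–target distance), and six regressors are
fitted and scored with R² (squared Pearson correlation), residual RMSE and
RPD = SD(measured)/RMSE. Feature sets are compared as VI, VI+TI, VI+PH and
VI+TI+PH. A random-forest wheat/soil mask (bands + NDVI, EVI2, REOSAVI,
OSAVI) restricts the final per-pixel inversion map to crop pixels.

Because the original field campaign data are not deposited, the package
ships a synthetic scene generator that reproduces the statistical structure
the method relies on; every stage is verified against it.

## The synthetic scene generator

`generate_scene()` builds co-registered rasters and a ground-sample table
from a `scene_config()`. The generator *is* the study condition for all
package-level verification, so its defaults are fixed and documented:

* **LAI field.** A Gaussian random field (FFT-smoothed white noise,
  smoothing scale 12 px) rank-mapped through the quantile function of a
  normal distribution with mean 3.89 and SD 1.93 truncated to
  [0.61, 8.57] — the summary statistics of the emulated campaign. Only the
  marginal distribution and smoothness are constrained; the paper-style
  field data give no spatial model, so smoothed noise is the neutral
  choice.
* **Plant height.** `PH = 5·LAI + 20` cm plus 2 cm Gaussian noise, clipped
  at zero. Jointing-stage wheat stands roughly 25–65 cm; the linear
  positive PH–LAI relation is the structural assumption the PH feature
  exploits. The bare-soil DSM is smooth terrain (~0.5 m relief); the
  jointing DSM adds PH in meters and 1 cm sensor noise.
* **Reflectance.** Beer–Lambert canopy cover mixing,
  `refl_b = f_b · veg_b + (1 − f_b) · soil_b + noise`, with
  `f_b = 1 − exp(−k · s_b · LAI)`, `k = 0.5` and band scales
  `s = (1.2, 1.8, 0.9, 0.7)` for G/R/RE/NIR. The band-specific extinction
  reflects that red light is absorbed most strongly by the canopy while
  NIR is scattered: the visible bands saturate first, which (i) produces
  the index saturation at high LAI the method is designed to overcome and
  (ii) keeps red-edge ratio indices (MTCI, CLre) responsive after red has
  saturated. With a single shared cover fraction, every band is the same
  linear function of cover and ratio-of-difference indices such as MTCI
  degenerate to near-constants — an unrealistic artifact.
  Canopy reflectance defaults (0.08, 0.05, 0.30, 0.50) and soil
  (0.10, 0.16, 0.20, 0.24) are field-typical spectra; additive noise SD is
  0.005 reflectance units.
* **Structure.** A sinusoidal row pattern (0.15 m spacing, 3% amplitude)
  modulates wheat-pixel reflectance; vertical bare-soil strips (8 px wide,
  every 64 px) give the masking stage both classes.
* **Ground samples.** `sample_ground_truth()` spreads n points (default
  79) by stratified grid jitter over the wheat mask, excluding a 2-px
  margin (field plots sit in the interior; moving-window features are then
  defined at every point). Measured LAI is the truth pixel value plus
  0.15 m²/m² noise (a plant-canopy-analyzer-scale error; the instrument
  error of the emulated campaign is unreported, so this is a free
  parameter). Measured PH is the mean truth height over wheat pixels
  within 0.5 m plus 2 cm tape noise, mirroring a protocol that averages
  representative plants inside a 50 cm circle.

What the generator does *not* emulate: atmospheric and bidirectional
reflectance effects, photogrammetric DSM artifacts, mixed pixels at row
scale, lodging, weeds, and any VI–LAI relationship beyond Beer–Lambert
mixing. Passing tests therefore demonstrate that the pipeline recovers
signal of the assumed structure — not field-level accuracy.

## Stage-by-stage numerical choices

**Rasters.** A minimal in-package container (matrix + lower-left origin +
square cell size; row 1 = north) with `NA` as nodata. Files use the ESRI
ASCII grid text format, written at 17 significant digits so round-trips are
bit-exact. Pixel-center conventions: a point belongs to the cell whose
index `floor()` yields; disc extraction averages cells whose centers lie
within the radius, with 1e-9 relative slack so exact-boundary cells behave
consistently under floating-point translation of the georeference.
Cubic-convolution resampling uses the Keys kernel (a = −1/2), reproduces
degree-≤1 polynomials exactly, replicates borders, and poisons any output
cell whose stencil touches nodata.

**Vegetation indices.** Division by zero and negative radicands yield
nodata, as does nodata in *any* input band. Formula choices where a
printed source is ambiguous: MSR = (NIR/R − 1)/√(NIR/R + 1); MSAVI and
MTVI2 with their square roots (MTVI2 with 5·√R); REOSAVI =
1.16(NIR − RE)/(NIR + RE + 0.16), the red-edge analogue of the OSAVI
pattern (OSAVI itself, red-band, is registered for masking); RERDVI =
(NIR − RE)/(NIR + RE) as commonly printed.

**GLCM texture.** Defaults: 3×3 window, 64 gray levels, offset (1, 1)
(distance one pixel; the diagonal is the common co-occurrence default
shift, configurable to the four canonical directions), symmetric counting.
Quantization is per-band min–max scaling to {0, ..., 63} with half-intervals
rounding down (`ceiling(u·(levels−1) − 0.5)`). Statistics use 0-based gray
levels directly; a zero-variance window reports correlation 0 (not nodata)
so constant regions stay usable; windows without a complete neighbourhood
or without any valid pair are nodata. The moving-window kernel is C++
(Rcpp); the single-window R implementation and an independent brute-force
pair-enumeration oracle pin both down in the tests.

**Texture indices.** NDTI and DTI are enumerated over unordered layer
pairs (swapping arguments only flips sign — including both would add
perfectly collinear duplicates), RTI over ordered pairs (the reciprocal is
a genuinely different predictor). 32 layers give 496 + 496 + 992 = 1984
definitions. No de-duplication of sign-equivalent TI is applied at
screening.

**Screening.** Two-sided Pearson t-test per feature; selection requires
|r| rounded to two decimals ≥ 0.80 (inclusive at the threshold — features
listed at exactly 0.80 are retained) and p < 0.01. Features undefined at
some samples are screened on their complete cases but only fully-finite
features may enter a model; constant features are excluded with a warning.
No multiple-testing correction is applied across the 1984 TI tests — the
emulated workflow applies none, and silently adding one would change the
selected sets.

**SPXY.** Features are z-scored before the feature-space distance (the
table mixes unitless indices with PH in cm; configurable off). The joint
distance is d_x/max(d_x) + d_y/max(d_y); selection is Kennard–Stone:
seed with the most distant pair, repeatedly add the sample maximizing the
minimum joint distance to the selected set, stop at round(0.7·N) (79 →
55). All ties break to the lowest sample index, making the split a pure
function of the table. Note the selection favors but does not force the
extreme-target samples: a sufficiently remote feature-space sample can
out-compete them, so the guarantee verified in tests is near-full coverage
of the target range.

**Regressors.** RF (500 trees, minimum leaf 8) via `randomForest`; XGBoost
stumps (eta 0.5, max_depth 1, gamma 0.01, alpha 0.02, lambda 0.1,
subsample 0.3, colsample_bytree 0.5) via `xgboost` with 100 rounds — the
round count is a package default chosen as a conventional budget for
stumps at this learning rate; epsilon-SVR (RBF) via `e1071` with cost and
gamma tuned on the full log-2 grid 2⁻⁸...2⁸ by deterministic 5-fold CV;
BPNN via `nnet` with one hidden layer of one node by default (as stated in
the emulated setup; almost certainly conservative, so the size is
configurable). The 1-D CNN (one convolution block, kernel = ⌈J/2⌉, 16
filters, ReLU, 20% dropout) and single-layer LSTM (16 hidden units,
reading the feature vector as a length-J sequence) are minimal in-package
implementations trained full-batch with SGD-momentum (lr 0.01, momentum
0.9, 300 epochs); their hand-derived backward passes are verified against
numerical gradients in the test suite. All fits take an explicit seed;
RF/XGBoost/SVM are bit-reproducible, the neural fits are seeded but
checked by tolerance. A zero-variance calibration target short-circuits
every algorithm to the exact constant predictor (the underlying libraries
cannot scale a zero-variance response).

**Evaluation.** R² is the squared Pearson correlation between measured and
predicted values. RMSE is the standard residual form
√(Σ(ŷᵢ − yᵢ)²/n) — the printed sum-of-squares-about-the-mean form in the
emulated source is the SD of predictions and cannot serve as an error, so
the residual form is used and the identity RPD·RMSE = SD(measured)
(population SD) is enforced by test. Perfect predictions report RPD = Inf;
zero-variance predictions report R² = 0 with a warning. Mask accuracy is
OA and Cohen's kappa from the 2×2 confusion matrix; single-class truth
makes kappa NA.

**Pipeline.** `run_experiment()` runs simulate → texture → features →
screen → split → train → evaluate, failing fast with the stage name.
Screening is performed once (VI and TI pools separately, PH always enters
the PH combinations unscreened); the SPXY split is recomputed in each
combination's own post-screening feature space, as the distance depends on
the features used. If no feature passes screening the single best-|r|
feature is used, with a warning, so small scenes degrade rather than
abort. `make_lai_map()` freezes the trained model's feature list,
assembles exactly those rasters, predicts on wheat-mask pixels and leaves
the rest nodata.

## Problem sizes and verification scope

Package-level verification uses 96–256 px scenes with 40–200 sample
points; the synthetic-recovery check runs the XGBoost pipeline on five
seeds at n = 200 points on the default 256×256 scene, and the
reproducibility check re-runs the full RF/XGBoost/SVM experiment twice and
compares the results table byte for byte. These sizes were chosen so the
whole suite and the acceptance script each complete in a few minutes on a
single CPU while still exercising every code path at realistic feature
dimensions (17 VI + 1984 TI candidates + PH).

## Known limitations

* The GLCM offset direction of the emulated workflow is a software default
  and not stated; (1, 1) is adopted and configurable. The pairing scheme
  behind the 1984 texture indices is likewise inferred (it is the unique
  natural scheme reproducing the count).
* The synthetic spectra are two-endmember mixtures; indices are therefore
  more mutually correlated than in field data, and screening selects more
  TI than a real campaign would.
* SVM tuning cost dominates pipeline runtime (1445 cross-validated fits);
  the grid follows the stated 2⁻⁸...2⁸ range and is not adaptive.
* The CNN/LSTM implementations are deliberately minimal (one block, fixed
  architecture); they are reference implementations for the comparison,
  not performance-tuned deep models.
* No reprojection: all inputs are assumed co-registered on a shared
  north-up square grid.
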