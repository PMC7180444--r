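---
title: "Region-based characterization of intraretinal cystoid fluid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based characterization of intraretinal cystoid fluid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intraretinal cystoid fluid — hyporeflective, roughly elliptical pockets that
accumulate between the retinal layers in exudative macular disease and
macular edema — is one of the main findings clinicians look for in optical
coherence tomography (OCT) B-scans. Pixel-accurate segmentation of these
pockets is often ill-posed: many cysts have blurred membranes, merge into
groups, or barely differ in contrast from the surrounding tissue. `octcyst`
instead takes a *regional* view: square windows sampled between the inner
limiting membrane (ILM) and the retinal pigment epithelium (RPE) are
classified as cystoid or non-cystoid from a rich intensity/texture
description, which is both more robust and directly useful for screening.

The pipeline has five stages, each an exported module surface:

1. **Retina delimitation** (`segment_ilm_rpe`): graph search for the ILM
   and RPE boundaries.
2. **Window sampling** (`extract_windows`, `label_window`,
   `build_dataset`): overlapping square windows inside the ROI, labeled
   against a reference cyst mask.
3. **Feature measurement** (`extract_features`): a 510-value descriptor
   per window, in a canonical layout (`feature_layout`).
4. **Feature selection** (`trace_ratio_rank`, `relief_f_rank`,
   `forest_importance_rank`): per-fold rankings of the most
   discriminative features.
5. **Evaluation** (`run_cv`, `accuracy_curves`, `best_results`,
   `category_presence`, `category_score`, `pairwise_correlation`):
   repeated stratified cross-validation over progressive feature subsets.

A seeded phantom generator (`phantom_spec`, `generate_bscan`,
`generate_dataset`) provides OCT-like B-scans with known boundaries and
cyst masks, so the whole chain can be validated without clinical data.

## Layer segmentation

The retina is delimited by the two strongest dark-to-light horizontal
boundaries. Pixels form a lattice graph; the weight of the edge between
pixels $a$ and $b$ is

$$w_{ab} = 2 - (g_a + g_b) + w_{\min},$$

where $g$ is the vertical dark-to-light gradient min–max normalized to
$[0,1]$ and $w_{\min} = 10^{-5}$ keeps weights positive. Dijkstra's
algorithm (implemented in C++ with a deterministic `(cost, row, col)`
tie-break) finds the cheapest left-to-right path; virtual endpoint columns
let the path start and end at any row. Moves advance one column
(diagonally or straight) or one row vertically within a column, so steep
boundaries remain reachable.

Numerical choices:

* The gradient uses a 5-pixel separable Gaussian pre-smoothing
  ($\sigma = 1$) followed by central differences (one-sided at the image
  border); smoothing can be disabled.
* Both the ILM and the RPE are dark-to-light edges. The first path locks
  onto the strongest one; a band of ±10 rows around it (configurable
  `exclusion_margin`) is excluded and the search repeated. The upper path
  becomes the ILM, the lower the RPE. Because the excluded band spans
  every column, the second path is provably on one side of the first, so
  the two never cross; a degenerate image where no feasible second path
  exists raises a typed error carrying the raw paths.
* On noise-free phantoms the recovered boundaries sit within one pixel of
  truth (the gradient peak is split symmetrically across the edge), and
  within the test suite's two-pixel bound at the default speckle level.

## Window sampling and labeling

Windows are squares of odd side $W$ (default 61) on a raster grid with
stride $W/2$ (configurable), kept only when the full block fits inside the
image and the center lies between the boundaries — no padding is ever
fabricated. A window is labeled cystoid when cyst pixels make up at least
$\tau = 0.05$ of its ROI-restricted area; the threshold is configurable,
and labeling is monotone in $\tau$ by construction. Class balance is
achieved by seeded down-sampling of the majority class.

## The 510-feature descriptor

Every window is described by eleven categories in a fixed layout
(GIBS 1–15, AIS 16–27, EIG 28–55, LESH 56–183, GLCM 184–199, HOG 200–280,
GABOR 281–408, LBP 409–472, LAWS 473–500, FD 501–503, GLRL 504–510). All
categories operate on the raw block; only the eigen-features restrict to
the largest rectangle inscribed in the window's ROI mask. Choices that the
literature leaves open are pinned as follows:

* **GIBS** — max, min, mean, median, standard deviation and variance
  (population convention), Shannon entropy in bits over the 256-level
  histogram, the 25th/75th percentiles (R type-7 quantiles), and a normal
  fit: $\hat\mu$, $\hat\sigma$ (MLE) plus 95% confidence bounds for each
  (t distribution for the mean, chi-squared for the spread).
* **AIS** — skewness and plain kurtosis ($m_4/m_2^2$) of every row and
  column, collapsed to min/mean/max; zero-variance series contribute 0 to
  both, keeping all values finite.
* **EIG** — singular values of the column-mean-centered ROI rectangle.
  Column centering (rather than grand-mean centering) keeps a rank-one
  pattern rank one. Non-square rectangles are covered by square windows
  of the shorter side at half-side stride, averaging the sorted spectra
  element-wise. Emitted: 4 largest, 4 smallest, two percentiles, the 16
  ratios $\lambda^{max}_i/\lambda^{min}_j$, and
  $\lambda^{max}_1/\lambda^{max}_4$, $\lambda^{min}_1/\lambda^{min}_4$;
  every $x/0$ or $0/0$ maps to 0.
* **LESH** — Kovesi-style phase congruency over a log-Gabor bank
  (5 scales, 8 orientations, minimum wavelength 3 px, multiplier 2.1,
  bandwidth parameter 0.55, angular spread $1.2 \times \pi/8$) with the
  Rayleigh noise model at $k = 2$ standard deviations and
  $\varepsilon = 10^{-4}$. Each pixel is labeled with its
  maximal-amplitude orientation; a 4×4 partition grid accumulates phase
  congruency into 8 orientation bins per partition (128 values,
  L2-normalized). The block is divided by its standard deviation first,
  which makes the descriptor *exactly* invariant to intensity scaling
  instead of approximately so (the $\varepsilon$ stabilizers would
  otherwise leave a residual of order $\varepsilon/\Sigma A$).
* **GLCM** — 8 gray levels by uniform binning of [0,255]; symmetric
  normalized matrices at distance 2 for 0°, 45°, 90°, 135° (rows grow
  downward); contrast, correlation (0/0 → 0), energy, homogeneity.
* **HOG** — 3×3 cells, 9 unsigned orientation bins with centers at
  0°, 20°, …, 160°, magnitude-weighted with linear interpolation
  (circular over 180°), per-cell L2 normalization
  ($\varepsilon = 10^{-6}$), no block renormalization.
* **GABOR** — 8 frequencies $f_k = 0.25/\sqrt{2}^k$ × 8 orientations
  $j\pi/8$; $\gamma = \eta = \sqrt 2$, $\sigma = 0.56/f$; complex kernels
  truncated at $\min(\lceil 2.5\sigma\rceil, 31)$ px half-width and
  applied by FFT with reflective padding; per filter the mean then the
  standard deviation of the response magnitude (64 + 64, frequency-major).
* **LBP** — rotation-variant codes for all 32 (neighbors, radius)
  combinations, $P \in \{4,8,12,16\}$, $R \in 1..8$, bilinear neighbor
  interpolation on fully-supported pixels only. The comparison is
  evaluated on interpolated *differences*, which makes the features
  bit-identical under a global intensity shift rather than merely close.
* **LAWS** — outer products of the classic 1-D kernels within each size
  family; transposed pairs averaged, the pure smoothing map dropped:
  5 maps (3×3) + 9 maps (5×5); energy = absolute response on the valid
  region; mean and standard deviation per map.
* **FD** — differential box counting on a 16×16 sliding window (stride
  8), grid scales {2,3,4,6,8} with partial edge cells included and box
  height $s \cdot 256 / 16$; each cell contributes
  $\lfloor(\max-\min)/h\rfloor + 1$ boxes — the span form, exactly
  shift-invariant, unlike the absolute-position form. The local dimension
  is the least-squares slope of $\log N$ vs $\log(1/s)$; lacunarity is
  variance/mean² of the finest-scale box masses. On a flat window the
  slope is exactly 2 only when every scale divides the window side; with
  the mixed scale set it is close to but not exactly 2, and the tests pin
  the value computed by an independent loop oracle rather than assuming
  the idealization.
* **GLRL** — 51 gray levels (`floor(g·51/256)`); run matrices of the four
  orientations summed before computing SRE, LRE, GLN, RP, RLN, LGRE,
  HGRE (levels 1-based in the emphasis terms; RP divides by the pixels
  scanned over all four orientations).

The Gabor block is summarized symmetrically — all 64 means followed by
all 64 standard deviations — since that is the only split consistent
with a bank of eight frequencies times eight orientations described by
two statistics per filter; an asymmetric 32/96 split cannot be
reconciled with such a bank.

## Feature selection

* **Trace ratio** — supervised Fisher-style affinity graphs (cross-class
  pair weight $1/n$, same-class weight $1/n_c$) reduce per feature to a
  between-class scatter $b_i$ and a within-class scatter $w_i$. The
  iteration $\lambda \leftarrow \sum_{sel} b / \sum_{sel} w$, re-selecting
  the $k$ largest $b_i - \lambda w_i$, converges monotonically to the
  subset maximizing $\sum b / \sum w$ (verified against exhaustive subset
  enumeration in the tests). Deterministic; ties break to the lower index.
* **Relief-F** — all samples probed (by default), 10 nearest hits and
  misses, Manhattan distances on z-scaled, range-normalized features,
  miss contributions weighted by class priors. Neighbor counts and probe
  counts are configurable since the canonical description leaves them
  open.
* **Forest importance** — impurity importances from an extremely
  randomized trees ensemble (ranger, `extratrees` split rule, no
  bootstrap), consuming raw features.

Features are z-scaled inside the selector for the two distance-based
methods; the forest is scale-invariant by construction.

## Evaluation protocol

`run_cv` performs repeated stratified k-fold cross-validation (default
10×10; stratification keeps both classes in every fold, which the
protocol requires). In each fold every selector is fitted **on the
training rows only**, then each classifier is trained on the nested
ranking prefixes of sizes 1..`max_features` (default 100) and scored on
the held-out fold; the leakage property (shuffling held-out labels cannot
change a fitted ranking) is asserted by construction in the tests.

The seven classifiers: LDA (MASS), an L2-ridge classifier (closed-form
least squares on ±1 targets, $\alpha = 1$, unpenalized intercept), linear
and RBF SVMs (e1071, $C = 1$, $\gamma = 1/(d \cdot \mathrm{var})$),
distance-weighted 15-NN, a 100-tree random forest (ranger), and gradient
boosting (xgboost, 100 depth-3 trees on the logistic loss). Features are
z-scaled per fold with training statistics for the linear/distance-based
classifiers; tree ensembles see raw features. Every stochastic component
draws its seed deterministically from the master seed.

Analytics mirror the protocol's standard reports: mean accuracy curves
with standard deviations, best mean accuracy per (selector, classifier)
with milestone subset sizes and the stabilization statistic (mean/sd of
successive-size differences over the last 50 sizes), absolute pairwise
feature correlations with category-pair means (self-pairs excluded,
constant features correlate 0 by convention), category presence in the
top-100 (absolute and proportional to `min(100, category size)`), and the
best-rank score $100(100 - r)/99$ mapping rank 1 to 100, rank 100 to 0,
and absence to −1.

## The phantom generator

The phantom emulates the image properties the pipeline relies on, not the
physics of interferometric capture:

* bright layered bands on a dark vitreous background, with a foveal dip
  (negative Gaussian, strongest at the ILM and decaying with depth) and a
  gentle random tilt/undulation;
* a hyporeflective zone above a bright RPE band, so the RPE is the
  second-strongest dark-to-light edge after the ILM;
* cysts as filled rotated ellipses with sigmoid-feathered borders
  (a 30% fraction gets heavier feathering to emulate blurred membranes),
  clipped strictly between the boundaries;
* drusen-like hyperreflective bumps deforming the RPE top (ground truth
  follows the deformation) and vertical shadow columns as multiplicative
  attenuation below their origin;
* multiplicative gamma speckle with unit mean (shape 16 by default,
  i.e. ~25% intensity contrast) and 8-bit quantization.

Defaults — 512×384 px, retina between rows ≈100 and ≈260, tissue at gray
130, fluid at 45, background at 25, five cysts of 10–40 px semi-axes, two
shadows at 0.6 attenuation, two drusen — are a desk-scale rendering of
the smaller clinically reported B-scan dimensions, calibrated only
qualitatively (no intensity statistics of clinical datasets are
published). `generate_dataset` jitters sizes ±15% and renders roughly
half the images without cysts.

What passing tests on phantoms do **not** show: robustness to real
speckle statistics (which are spatially correlated, not i.i.d. gamma), to
device-dependent contrast curves, to pathology beyond the
cyst/shadow/druse triad, or to segmentation failure modes caused by
vitreous detachments and large deformations. The phantom benchmark is a
functional test of the pipeline's mechanics and relative feature
behavior, not a clinical validation.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own defaults: 20 phantoms for layer recovery, 40
images / 420 balanced windows for the end-to-end benchmark with 5×2 CV
over the Relief-F + RBF-SVM configuration and subset sizes up to 50, and
oracle suites of dozens of small random blocks per texture family. All
random draws — phantom content, fold assignment, probe subsets, tree
ensembles, balancing — derive from a single master seed, and identical
seeds give bit-identical outputs end to end.

## Known limitations

* The exclusion margin between the two boundary paths (10 rows) and the
  labeling threshold $\tau$ are defaults, not estimated quantities.
* Eigen-features on very thin ROI rectangles (< 4×4) fall back to a
  zero-padded spectrum with a warning.
* Phase congruency operates on the raw block FFT, so image borders are
  implicitly periodic; partitions touching the border can pick up
  wrap-around energy on synthetic images with non-matching edges.
* The kNN classifier stores the full training fold (no indexing
  structures); at the intended window counts (hundreds to a few
  thousand) this is not a bottleneck.
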