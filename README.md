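# octcyst

Region-based characterization of intraretinal cystoid fluid in OCT
B-scans.

Intraretinal fluid pockets — hyporeflective, roughly elliptical regions
between the retinal layers — are a key finding in exudative macular
disease and macular edema. Segmenting them pixel by pixel is often
ill-posed (blurred membranes, merged groups, poor contrast), so `octcyst`
classifies *regions* instead: square windows sampled between the inner
limiting membrane (ILM) and the retinal pigment epithelium (RPE) are
described by a 510-value intensity/texture battery and classified as
cystoid or non-cystoid. The package is aimed at researchers in retinal
image analysis who want a transparent, fully seeded re-implementation of
this regional pipeline, plus a phantom generator to exercise it without
clinical data.

## The method

1. **Retina delimitation.** Pixels form a lattice graph with edge weights
   `w(a,b) = 2 − (g_a + g_b) + w_min`, where `g` is the vertical
   dark-to-light gradient normalized to [0,1]. Dijkstra's algorithm (C++,
   deterministic tie-breaks, virtual endpoint columns) finds the
   minimum-cost left-to-right path — the strongest boundary. A ±10-row
   band around it is excluded and the search repeated; the upper path is
   the ILM, the lower the RPE.
2. **Sampling.** Overlapping `W × W` windows (default `W = 61`, stride
   `W/2`) whose centers lie in the ROI; a window is cystoid when cyst
   pixels cover ≥ τ = 0.05 of its ROI-restricted area.
3. **Features.** Eleven categories in a canonical 510-slot layout:
   global intensity statistics (GIBS), axis skewness/kurtosis (AIS),
   eigen-spectra of the inscribed ROI rectangle, local energy-based shape
   histograms (LESH, phase congruency over a log-Gabor bank), gray-level
   co-occurrence statistics (GLCM, distance 2, four angles), histograms
   of oriented gradients (HOG, 3×3 cells × 9 bins), a Gabor bank
   (8 frequencies × 8 orientations, mean + sd), local binary patterns
   (LBP, 32 neighbor/radius configurations, mean + sd), Laws' texture
   energies (14 maps, mean + sd), differential box-counting fractal
   features (mean, sd, lacunarity), and gray-level run-length statistics
   (GLRL: SRE, LRE, GLN, RP, RLN, LGRE, HGRE).
4. **Selection.** Three rankers fitted per training fold: the iterative
   trace-ratio criterion (maximizing Σb/Σw over subsets), Relief-F, and
   extremely-randomized-trees importance.
5. **Evaluation.** Repeated stratified k-fold cross-validation; per fold,
   each of seven classifiers (LDA, L2-ridge, linear/RBF SVM,
   distance-weighted 15-NN, random forest, gradient boosting) is trained
   on nested ranking prefixes of sizes 1..100 and scored on the held-out
   fold, yielding accuracy-versus-subset-size curves, best-result tables
   and category-relevance reports.

A seeded phantom module generates OCT-like B-scans (layered bands, foveal
dip, gamma speckle, feathered elliptical cysts, shadow columns,
drusen-like bumps) with exact ground truth.

## Worked example

```r
library(octcyst)

p <- generate_bscan(phantom_spec(seed = 7))
p$image
#> <bscan 'phantom-7'> 384 x 512 px, gray range [6, 255]

b <- segment_ilm_rpe(p$image)
b
#> <layer_boundaries> 512 columns; ILM rows 100-125, RPE rows 243-259
mean(abs(b$ilm_row - p$truth$ilm_true))   # layer recovery error, pixels
#> [1] 0.57

ds      <- generate_dataset(phantom_spec(), n_images = 6, seed = 7)
rois    <- compute_rois(ds)
samples <- build_dataset(ds, rois = rois, seed = 7)
dplyr::count(samples, label)
#> 1 cystoid        92
#> 2 non_cystoid    92

feats <- extract_feature_table(ds, head(samples, 80), rois = rois)
rk <- relief_f_rank(feats[feature_layout()$name], feats$label, k = 10)
head(tidy(rk), 3)
#>    rank index name                score
#> 1     1     2 gibs.min            0.281
#> 2     2   408 gabor.sd.f8.o8      0.249
#> 3     3   190 glcm.correlation.90 0.238

cv <- run_cv(feats, cv_config(n_folds = 2, n_repeats = 2,
                              max_features = 10, selectors = "relief_f",
                              classifiers = c("svm_rbf", "random_forest"),
                              seed = 7))
glance(cv)[, 1:4]
#> 1 relief_f random_forest         0.874         9
#> 2 relief_f svm_rbf               0.887        10
```

The recovered boundaries sit about half a pixel from the phantom truth;
the minimum gray level (cysts are hyporeflective) and high-frequency
Gabor/GLCM statistics top the Relief-F ranking, and even 10 features give
~0.88 cross-validated accuracy on this small set. `autoplot(cv)` draws
the accuracy curves; `plot_bscan(p$image, b, p$truth$cyst_mask)` shows
the scan with its boundaries and mask.

A command-line front end with `phantom | extract | evaluate` subcommands
is installed at `system.file("cli", "octcyst", package = "octcyst")`.

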