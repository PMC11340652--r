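# oliveshape

Automated discrimination of olive (*Olea europaea*) cultivars from the
shapes of their fruits, leaves and endocarps (the woody stones). Cultivar
identification in olive germplasm collections is still largely done by
visual inspection of exactly these organs; `oliveshape` replaces the manual
scoring with a measurement-and-classification pipeline:

1. **Segmentation** — single-organ photographs or scans on a uniform
   background are thresholded (Otsu), cleaned and calibrated (mm per pixel,
   or `25.4 / dpi` for scans) into binary silhouettes.
2. **Contour geometry** — each silhouette becomes a closed boundary polygon,
   resampled at equal arc length and pose-normalized (centroid at the
   origin, principal axis vertical, apex up). Primitives: area, perimeter,
   caliper height/width and the width profile, a direct least-squares
   ellipse fit, Savitzky–Golay signed curvature, apex/base landmarks, and
   mirror-overlap symmetry measures.
3. **Descriptor catalogs** — 24 fruit, 16 leaf and 22 endocarp descriptors
   per sample (optionally 25 for endocarps), including the classical
   cultivar keys: shape index (elongation), circularity
   4&pi;A/P&sup2;, fitted-ellipse axes, nipple index and size, mucro
   signal (apex-curve area), petiole length and thickness, vertical and
   transversal symmetry.
4. **Classification** — per-organ probabilistic classifiers
   (gradient-boosted trees by default; random forest, k-NN and SVM
   available) are combined by a **stacking meta-classifier**: a stratified
   1/10 of the samples is held out, the rest is split into 5 folds whose
   out-of-fold class-probability matrices (3 organs × k cultivars wide)
   train the meta-classifier, which is then cross-validated and scored on
   the untouched holdout.
5. **Attribution** — exact (coalition-enumeration) and Monte-Carlo
   permutation **Shapley values** quantify each descriptor's contribution
   to the model output, and — applied to the meta-classifier's probability
   inputs — the contribution of each *organ* to each cultivar's
   identification.
6. **Exploratory statistics** — standardized PCA, coefficient-of-variation
   tables across sampling years (trait stability), Ward dendrograms of
   cultivar mean phenotypes (Newick export) and violin-plot summaries.

Because no public image set of this kind is deposited, the package ships a
**synthetic silhouette generator** (`generate_shape`, `generate_leaf`,
`generate_cohort`, `preset_cohorts`): star-shaped polar curves — an ellipse
modulated by an egg taper, apex sharpening, a Gaussian apex bump
(nipple/mucro) and band-limited boundary noise — with analytic ground truth
by quadrature. Every stage of the pipeline is tested against that ground
truth.

## Worked example

```r
library(oliveshape)

co <- generate_cohort(preset_cohorts("separable3"), n_per_organ = 10,
                      years = c(1, 2), seed = 42)
head(co$fruit[, c("sample_id", "cultivar", "year", "A_height",
                  "A_shape_index", "A_circularity", "A_nipple_index")], 3)
#>         sample_id cultivar year A_height A_shape_index A_circularity A_nipple_index
#> 1 elongata_y1_001 elongata    1 28.55244      2.059428     0.8016937              0
#> 2 elongata_y1_002 elongata    1 26.94391      2.085271     0.7998201              0
#> 3 elongata_y1_003 elongata    1 29.01683      2.174708     0.7756014              1

fit_fruit <- train_base(co$fruit, seed = 1)
fit_fruit
#> <olive_base> xgboost on fruit features; CV accuracy 0.983 +/- 0.037 (3 classes)

joint <- pair_organs(co$fruit, co$leaf, co$endocarp, seed = 1)
model <- olive_stack(joint, seed = 1)
model
#> <olive_stack> 3 cultivars; meta random_forest over xgboost base classifiers
#>   meta-CV accuracy 1.000; holdout accuracy 1.000 (n = 6)

organ_contribution(model, joint, seed = 1)
#>    cultivar     fruit      leaf  endocarp
#> 1  elongata 0.3110189 0.3377256 0.3512555
#> 2 papillata 0.2827055 0.3512026 0.3660919
#> 3 sphaerica 0.3412626 0.2991402 0.3595972   # weights per row sum to 1
```

Reading the output: each fruit row carries the 24 shape descriptors of the
two standardized viewing positions (A/B); `A_shape_index` ≈ 2.1 marks the
elongated cultivar, and `A_nipple_index` flags a detected apex teat. The
fruit-only classifier reaches 98% cross-validated accuracy on this easy
three-cultivar panel, the stacked model classifies the untouched holdout
perfectly, and — since all three organs are informative here — the organ
contributions are near-uniform. On the `kalamon_leaf` preset, where one
cultivar differs only in its leaf, that cultivar's leaf weight rises to
≈ 0.9.

A thin command-line wrapper covers the same pipeline
(`inst/scripts/oliveshape`): `segment`, `features`, `synth`, `train`,
`evaluate`, `curve`, `importance`, `stats`; every run writes a
`manifest.json` from which its outputs can be reproduced.

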