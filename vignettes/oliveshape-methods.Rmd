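---
title: "Shape-based olive cultivar discrimination: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based olive cultivar discrimination: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveshape)
```

`oliveshape` turns binary silhouettes of olive fruits, leaves and endocarps
into quantitative shape descriptors, classifies cultivars with a stacking
ensemble over per-organ classifiers, and attributes decisions to descriptors
and organs with Shapley values. This vignette explains the underlying
models, the tunable parameters and the choices made where the design was
genuinely open. It states no empirical result beyond what the package's own
tests and `scripts/acceptance.R` compute.

## From image to silhouette

An input image is assumed to contain one dominant object on a uniform
background. `segment_image()` applies a global Otsu threshold to the
intensity histogram; the foreground polarity (dark object on light or the
reverse) is chosen automatically, requiring that the object touch fewer
than three image borders. Holes are filled, components below 1% of the
largest are discarded as specks, and the largest 4-connected component is
kept. A valid silhouette must have a single 4-connected foreground of at
least 100 pixels that touches no border.

The physical scale is supplied by the user (`mm_per_px`, or `25.4 / dpi`
for flatbed scans); no attempt is made to read a ruler out of the image —
the hardware setups that produce such images differ too much for a single
detector to be reliable, and mis-read scales would corrupt every
size descriptor silently.

## Contour model

`contour_from_silhouette()` traces the 0.5-level set of the mask (sub-pixel,
by linear interpolation between pixel centers), smooths it with a circular
Gaussian of σ = 1 px along arc length, and resamples it to `n_points`
(default 512) at equal arc length. The 1-px smoothing exists to remove the
rasterization staircase: without it the perimeter of a rasterized disc is
inflated by several percent and circularity is biased low; with it, disc
circularity is correct to well under 2% while areas of features larger than
a few pixels are essentially unbiased.

The pose is then normalized: centroid at the origin, first principal axis
of the boundary points vertical, orientation counter-clockwise, apex up.
Apex-up disambiguation uses the **maximum** absolute curvature over the
landmark window (±10% of perimeter) at either vertical extreme: the sharper
end is the apex. The window *mean* was considered and rejected — a fruit
nipple flattens the curve on its flanks, and averaging can pull the bump
end's mean curvature below the plain end's, flipping the shape. For leaves
the petiole attachment defines the base instead and is passed as
`base_point`.

Equal-arc-length resampling at a fixed `n_points` makes curvature windows
and mirror overlaps comparable across samples; areas computed at 256 versus
1024 points agree to well under 0.5%.

## Geometric primitives

* **Area/perimeter** — shoelace formula and segment sums on the closed
  polygon.
* **Caliper dimensions** — height is the y-extent; the width profile is the
  horizontal chord length as a function of normalized height (256 levels);
  width is the profile maximum.
* **Ellipse fit** — the direct least-squares conic fit constrained to
  ellipses, in the numerically stable partitioned formulation. Points are
  mean-centered before fitting. The residual is the root-mean-square radial
  distance (exact point-to-ellipse distance has no closed form; the radial
  approximation is accurate for the low-eccentricity, near-centered contours
  seen here).
* **Curvature** — signed curvature from Savitzky–Golay first and second
  arc-length derivatives (cubic, window 15 of 512 points, circular
  padding). Convex arcs of the counter-clockwise contour are positive. The
  window is part of every descriptor's definition and is reported; curvature
  is exported nondimensionalized (κ × length) so it is scale-free.
* **Symmetry** — transversal asymmetry is one minus the fractional overlap
  of the shape with its mirror image about the vertical axis, computed on a
  0.05 mm/px rasterization (a resolution-stated, intersection-free
  implementation); vertical symmetry is the normalized height of the widest
  chord.

## Descriptor catalogs

The catalogs contain 24 fruit, 16 leaf and 22 endocarp descriptors (25 with
the extended endocarp flag — the two counts circulating for endocarps are
reconciled by making the 3 cross-position extras optional). They include
every classical cultivar key — shape index, circularity, fitted-ellipse
axes, nipple index/size, mucro signal, petiole dimensions, symmetry
measures, base length, transversal-diameter position — and fill the
remaining slots with standard morphometrics (perimeter, convexity, ellipse
major axis). The exact formulas are this package's own reconstructions;
they are documented in the function reference and marked as such.

**Nipple detection** compares the apex landmark window against the arc of a
robust ellipse baseline. A plain least-squares fit will not do as baseline:
the bump drags the semi-major axis up until the ellipse passes near the
bump tip (a classic masking effect), and excluding the whole apex cap makes
the semi-major axis ill-conditioned instead (the fit overshoots the height
by several percent). The baseline is therefore a trimmed refit: fit all
points, drop points whose outward radial residual exceeds 2.5 robust
standard deviations (at most 15% of the contour), refit, twice. A nipple is
declared when (i) the maximum outward deviation exceeds 2% of the height,
(ii) the deviation region — contiguous points above 10% of the maximum
deviation — occupies less than 80% of the window (a pointed apex deviates
broadly; a teat is local), and (iii) the region contains a curvature spike
at least twice the window median, evaluated on a lightly smoothed
(7-point) curvature so narrow teats are not averaged away. Nipple size is
the polar-integral area between contour and baseline arc over the region;
whether the literature's "nipple size" is an area or a length is not
documented anywhere we could find, so the area convention is used and
stated. The same deviation integral over the full apex window, without the
locality conditions, is the endocarp's `apex_curve_area` (mucro signal);
`mucro_index` flags it at 1% of the organ area.

**Petiole splitting** projects foreground pixels onto the principal axis
and takes the maximal terminal run of the width profile below 20% of the
maximum width, if longer than 5% of the organ; upper/lower thickness are
mean widths over the quarter adjoining the blade and the distal quarter.

## Synthetic generator

The generator defines the study conditions for every test. Shapes are
star-shaped polar curves

ρ(θ) = r_ellipse(θ; width/2, height/2) · (1 − taper·sin θ) · pinch(θ) +
bump(θ) + noise(θ),

with the apex at θ = π/2. `taper` > 0 moves the widest section toward the
base (the conventional egg asymmetry); `pinch` multiplies the apex-half
shoulders by 1 − ½(1 − 1/apex_sharpness)·sin²2θ, which reduces to the pure
ellipse at sharpness 1 and sharpens the apex above it; the bump is a
Gaussian in angle (default σ = 0.18 rad — a localized teat, which is what
distinguishes a nipple from mere pointedness) with amplitude expressed as a
fraction of height; the noise is a band-limited Fourier series (orders
6–12) with amplitude a fraction of width, capped at 5%. Because ρ > 0 is
enforced, the polygon is always simple. Ground truth (area, height, width,
widest-section height, bump area) comes from quadrature of the curve at
4096 angles — independent of rasterization and of the measurement pipeline.

Cohorts draw per-sample parameters as lognormal perturbations of cultivar
means (lengths stay positive), with a per-sample latent size factor shared
between fruit and endocarp (cultivars with bigger fruits have bigger
stones, and the pairing of fruit with endocarp rows by sample id is thereby
meaningful) and a multiplicative year effect on all lengths in the second
sampling year. Typical defaults: within-cultivar relative sd 6–10%,
year effect 3–7%, boundary noise ~1% of width — chosen once as plausible
for nursery material grown under shared conditions.

Four presets fix the scenarios used in tests: `separable3` (wide gaps,
3% spread, 3% year effect — a cohort any competent classifier must solve
perfectly), `overlap14` (a 14-cultivar panel with graded sizes and shapes
at 10% spread; leaves overlap heavily so the leaf classifier is the weakest
organ and only the one wide-leaved cultivar stands out — the qualitative
structure reported for real Greek/Spanish panels), `kalamon_leaf` (fruit
and endocarp means identical across cultivars; only the leaf separates the
planted cultivar) and `complementary` (fruit separates {c1, c2} from c3,
endocarp separates c1 from c2, leaves are uninformative — the scenario in
which stacking must beat every single organ).

What passing on these cohorts does **not** show: robustness to shadows,
specular highlights, touching or overlapping organs, color and texture
variation, perspective distortion, or mis-calibrated scales. The generator
emulates silhouette geometry only.

## Classification

Per-organ classifiers (`train_base`) z-score features with statistics fit
on training folds only and report stratified 5-fold cross-validated
accuracy. Backends: gradient-boosted trees (default), random forest, k-NN,
RBF-SVM with probability calibration. Gradient-boosted trees use
`tree_method = "exact"`: on small cohorts the histogram method places split
thresholds flush against the training values bordering an empty
inter-class margin, so clearly separated test points just inside the margin
are confidently misclassified; exact greedy splitting cuts the margin at
its midpoint. All backends run single-threaded with derived seeds, and
class-probability ties are broken by fixed order, so identical seeds give
bit-identical reports.

The stacking procedure (`olive_stack`): (1) stratified 1/10 holdout;
(2) stratified 5-fold generation of out-of-fold probability matrices on
the remaining 9/10 — for each fold the three organ classifiers train on the
other 4/5 and predict the held fold, so no probability row is produced by a
model that saw it; (3) the meta-classifier trains on the concatenated
probability vectors (3 × k inputs); (4) cross-validation on that meta
training set gives the headline metric, and the holdout — scored with base
models refit on the full 9/10 — is reported separately. Both numbers are
reported because "the accuracy of the meta-classifier" can mean either.

The **meta-classifier default is a random forest** while the base default
stays gradient boosting. When the meta-training probabilities are separable
— the usual case on clean cohorts — greedy boosting achieves zero residual
with splits on a single organ's probability block and never diversifies,
so one wrong organ sinks an instance; bagged trees with random feature
subsets vote across all organ blocks. k-NN and boosting remain selectable.

Joint instances pair fruit and endocarp rows by shared sample id
(biologically grounded: the stones come from the sampled fruits) and leaves
by a seeded random permutation within cultivar, with the per-cultivar count
the minimum across organs. The leaf pairing is arbitrary by necessity —
there is no physical correspondence between an individual leaf and an
individual fruit — and is therefore resampled across repeated evaluations
so no result depends on one particular pairing.

`evaluate_stacking` repeats the whole procedure over seeded resplits
(default 10) to produce per-cultivar precision/recall/F1 as mean ± sd;
`accuracy_vs_k` draws seeded cultivar subsets (default 20 per k) and
reports per-organ and stacked accuracy as a function of panel size.

## Shapley attribution

The value function is interventional: v(S) is the mean model output with
coalition features set to the explained instance and the rest drawn from
background rows (a seeded subsample, ≤ 100 rows). `shapley_exact`
enumerates all 2^m coalitions (refusing m > 14) and satisfies local
accuracy and symmetry exactly; `shapley_sampled` is the permutation
estimator — mean marginal contribution over seeded random feature orderings
— with per-feature Monte-Carlo standard errors. Multiclass models are
explained per class on the predicted probability; global importance is the
mean absolute value across instances and classes (the "spread" — a wider
spread of Shapley values means the feature moves the model output more).

Organ contributions apply the same machinery to the meta-classifier's
probability inputs: for each cultivar, an organ's weight is the mean
absolute Shapley value summed over that organ's probability columns for
that cultivar's instances, normalized across the three organs. With k ≤ 4
cultivars the 3k meta inputs allow exact enumeration; wider panels fall
back to the sampled estimator. A tree-specific explainer from an external
library is deliberately not the implementation path; it may serve as an
independent cross-check only.

## Exploratory statistics

Features are z-standardized before PCA and clustering — the catalogs mix
mm², mm and unitless quantities, and raw-covariance PCA would be dominated
by areas. Sample (n−1) standard deviations are used throughout; CV is
sd/|mean| with NA below |mean| = 1e-12 or n < 3. The cultivar dendrogram is
Ward linkage on Euclidean distances between per-cultivar mean vectors of
the concatenated standardized organ descriptors, exported as Newick via
`ape`. Violin summaries remove outliers beyond 1.5 × IQR per group before
Gaussian kernel density estimation (Silverman bandwidth, 128-point grid);
groups under 5 points report quartiles only.

## Numerical choices and degenerate inputs

* Tie-breaking in classification is by fixed class order; all stochastic
  steps derive their seeds from one master seed by stable hashing.
* Segmentation errors out on uniform images and sub-100-pixel foregrounds;
  a second object above 25% of the largest triggers a warning rather than
  silent deletion.
* Constant features are dropped (with a warning) before PCA and are
  neutral in z-scoring (sd clamped to 1); they receive zero Shapley value
  by the null-player property.
* Curvature windows must stay below half the contour length; the mirror
  overlap and the generator's rasterization state their grid resolutions
  (0.05 mm/px) since both quantize space.
* Feature extraction failures for a sample are logged and the sample
  skipped — never imputed.

## Problem sizes

The shipped tests exercise the geometry oracles on 50 seeded shapes,
ground-truth round trips on 50 noiseless and 50 noisy shapes, stacking on
cohorts of 8–10 samples per cultivar and year (2 years), the 14-cultivar
panel at 15 samples per cultivar-year with 4 subsets per panel size, and
Shapley cross-checks at 10,000 permutations. These sizes were chosen so the
statistical properties under test are clearly resolved while the whole
suite stays comfortably interactive; all of them scale up linearly via the
corresponding arguments.

## Known limitations

* The descriptor formulas are reconstructions of classical morphometric
  keys, not a port of any particular published implementation; absolute
  descriptor values are not comparable to other tools, only the pipeline's
  internal contrasts are.
* Nipple/mucro detection on strongly pointed, noisy apexes is imperfect by
  nature — pointedness and small teats overlap physically. The detector's
  thresholds (2% of height, 2× curvature spike, locality) are stated
  constants, and the binary flags should be read together with
  `nipple_size` / `apex_curve_area`.
* The leaf-to-fruit pairing within a cultivar is random; any analysis that
  would depend on a *true* per-tree pairing is out of reach.
* Elliptic Fourier descriptors, landmark (Procrustes) morphometrics, color,
  texture and endocarp groove patterns are out of scope.
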