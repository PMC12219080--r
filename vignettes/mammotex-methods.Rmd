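---
title: "Texture-based mammogram classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based mammogram classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mammotex implements a complete computer-aided-diagnosis pipeline for
two-class (normal versus abnormal) mammogram classification: shearlet-domain
enhancement, breast/ROI segmentation by variance-weighted Otsu thresholding
plus Canny edge refinement, a 49-element hybrid texture descriptor, and a
convolutional network with a bidirectional LSTM head that can fuse the
handcrafted descriptor with its learned representation. A seeded phantom
generator stands in for clinical data so that every stage is exercised by
reproducible, fully labelled inputs. This vignette records the models, the
parameters that matter, and the design decisions taken where the procedure
left genuine freedom.

## Preprocessing

Images are resized to the 224 x 224 working resolution by separable bilinear
interpolation with pixel-centre alignment (`resize_image()`), so constants
are preserved and same-size resizing is the identity. Contrast stretching
(`contrast_stretch()`) maps the observed range linearly onto `[0, 255]`; a
constant image has nothing to stretch and maps to zero with a warning —
any choice is arbitrary here, and an explicit, tested one beats a silent
one. A 3 x 3 median filter (`median_filter3()`) suppresses impulse noise;
borders are handled by edge replication because zero padding would
manufacture a dark frame that a later global threshold would latch onto.

### Shearlet enhancement

The enhancement step operates in a cone-adapted, band-limited shearlet
frame built from Meyer-type windows (`build_shearlet_system()`). Radial
dyadic bands are produced by telescoping smooth step functions (so their
squared sum is exactly one), and each band is split angularly by shear
windows `g(2^j s - k)` whose squared integer translates also sum to one;
scale `j` carries shears `k = -2^j, ..., 2^j` on each of the two frequency
cones. The squared filter magnitudes therefore form an exact partition of
unity — a Parseval frame — which makes inversion trivial (multiply each
band by its own filter in frequency and sum) and testable: reconstruction
is exact to floating-point, and the test suite asserts `1e-6`. Individual
sheared bands are complex-valued; the bands at shears `+k` and `-k` are
conjugate mirrors, and their squared magnitudes still tile frequency
exactly.

Enhancement multiplies the band coefficients of the finest two scales by a
gain of 1.5 (`shearlet_enhance()`, `enhance_params()`). Because analysis
and synthesis are both diagonal in frequency, the full round trip collapses
to one frequency multiplier built from per-scale energies; the result is
identical to the explicit band-by-band route but roughly an order of
magnitude cheaper. Defaults — three scales, gain 1.5 on the finest two —
were chosen once: gains near 1.5 sharpen mass boundaries visibly without
overflowing the 8-bit range, and a unit gain provably reproduces the input,
which anchors the tests. The enhancement step has no free parameters fitted
to data.

## Segmentation

`crop_breast_region()` thresholds at 5% of the intensity ceiling, keeps the
largest 8-connected component, and optionally removes a pectoral-muscle
wedge. The wedge heuristic is deliberately narrow: a high-intensity region
whose connected bright pixels reach a top image corner and cover 2-40% of
the breast component. Mammogram pectoral shadows are corner-anchored bright
triangles; the area bounds stop the heuristic from eating a uniformly
bright breast. Detected wedge rows are cleared from the anchored corner out
to the furthest detected pixel plus a 2-pixel margin, so noisy stragglers
at the wedge boundary go with it.

`improved_otsu_threshold()` implements a variance-adaptive variant of
Otsu's method: each pixel contributes to the intensity histogram with
weight `1 + alpha * v(x) / max(v)`, where `v` is the local variance over a
`window x window` neighbourhood (defaults `alpha = 1`, `window = 15`,
computed with integral images). Textured pixels — mass borders,
spiculations — thus pull the between-class-variance optimum toward
separating them. `alpha = 0` recovers classical Otsu exactly, which is the
lever the test suite uses: the weighted path is checked against an
independent exhaustive classical search at `alpha = 0`, and the weighted
threshold is checked to move without degrading lesion overlap on a
textured-lesion phantom. Ties in the exhaustive search resolve to the
smallest maximising threshold; the mask convention is foreground strictly
above the threshold, since lesions are bright.

`canny_edges()` is a standard Canny chain — Gaussian smoothing
(`sigma = 1.4`), Sobel gradients, non-maximum suppression, dual-threshold
hysteresis — with two specifics. The hysteresis thresholds are fractions
(defaults 0.1 and 0.3) of the maximum gradient magnitude, so they adapt to
image contrast. Suppression compares each pixel against magnitudes
*interpolated* along the true gradient direction rather than a quantised
45-degree sector, and any remaining solid 2 x 2 response block is broken by
dropping its weakest member; both choices keep edges one pixel wide across
their normal, which the suite asserts (no 2 x 2 blocks; a disk's ring count
within 15% of its circumference).

`extract_roi()` closes the union of the threshold mask and the edge mask
with a 3 x 3 structuring element, takes the largest 8-connected component,
and returns its bounding box expanded by `pad` (default 8 px) and clipped
to the frame. On phantoms this box is essentially the breast region and
always contains the lesion, which is the property the tests check.

## Hybrid texture descriptor

Descriptors are computed on the ROI crop, quantised to `Ng = 32` gray
levels over the crop's own range (`quantize()`); 32 levels keep
co-occurrence matrices well populated at ROI sizes of a few hundred pixels
squared while preserving texture detail, and the oracles in the test suite
run at 4-8 levels where brute force is cheap. Levels are 1-based so the
low-gray-level run emphasis (`1/i^2`) is defined at the lowest level.

The 49-element vector (`assemble_hybrid()`) concatenates:

* five first-order histogram statistics — mean, skewness, entropy
  (base 2), uniformity, and smoothness `1 - 1/(1 + sigma_n^2)` with the
  intensity SD rescaled to `[0, 1]`;
* six co-occurrence descriptors (energy, contrast, entropy, homogeneity,
  correlation, cluster shade) for each of the four principal directions at
  pixel distance 1, computed from symmetrically accumulated, normalised
  matrices (`compute_glcm()`, `glcm_features()`). Symmetric accumulation is
  standard Haralick practice; the asymmetric mode remains available and is
  what the rotation-consistency test uses. Descriptors whose closed forms
  the source material only names — homogeneity, correlation, entropy,
  shade — follow the standard Haralick definitions;
* five run-length descriptors (short- and long-run emphasis, low- and
  high-gray-level run emphasis, gray-level non-uniformity) per direction
  from maximal-run counts along rows, columns, and both diagonals
  (`compute_glrlm()`, `glrlm_features()`), the standard Galloway set.

Degenerate inputs are contracts, not surprises: constant textures report
zero correlation and skewness with warnings; `0 log 0` is 0; every builder
is checked exactly against an independent brute-force oracle.

## The classifier

`bilstm_cnn_spec()` encodes the layer plan: five convolution blocks (7x7
kernels, a final 5x5; 3/512/256/128/64 channels), ReLU after every
convolution, 4x4 stride-2 max pooling after blocks 2-5, dropout 0.25 after
the first two pooling stages, a flatten into a sequence of scalars, a
bidirectional LSTM with 64 hidden units per direction concatenated to 128,
dropout 0.5, a 128-unit dense layer and a 2-way softmax. Two printed-plan
ambiguities were resolved as follows and are asserted by the shape tests:

* a stride-1 7x7 convolution cannot take 224 to 150, so block 1 convolves
  (224 to 218) and then resamples its maps to 150 x 150 with the same
  deterministic bilinear operator used for images — after which every
  subsequent printed size (144, 71, 65, 31, 25, 11, 7, 2, sequence 256)
  follows from standard convolution arithmetic, `floor((F - W + 2P)/s) + 1`;
* pooling uses a 4x4 kernel at stride 2, the only reading that reproduces
  those sizes.

When feature fusion is enabled the z-normalised 49-vector is concatenated
to the recurrent output ahead of the dense stack (`fusion_dim = 49`), so
the head sees both learned and handcrafted evidence. Normalisation is
fitted on training folds only (`fit_feature_scaler()`).

The engine is compiled (single-precision im2col + GEMM convolutions,
cached-state BPTT through both LSTM directions, Adam) and draws *all* of
its randomness — initialisation, epoch shuffling, dropout — from one
explicit Mersenne-Twister stream, so a `(data, config, seed)` triple yields
bit-identical parameters and predictions. Backpropagation is verified
against central finite differences on a small configuration; agreement is
limited only by single precision.

`channel_scale` multiplies every convolution's channel count (floor 1)
while leaving spatial arithmetic untouched. The package's own evaluation
runs use `channel_scale = 0.125`, which preserves the architecture's shape
behaviour at a fraction of the cost; the full-width plan is available by
setting 1.

Training defaults follow the reference protocol (Adam, learning rate
0.001, minibatch 32, categorical cross-entropy). For the phantom study the
package uses a small-sample protocol — 10 epochs, learning rate 0.002,
minibatch 4 — chosen by watching training-loss convergence on 80-image
folds: with only a few dozen gradient steps per epoch at minibatch 32, the
head cannot reach the plateau its own training loss indicates, while
smaller batches supply more optimisation steps at identical compute.
Early stopping is deliberately not implemented: a fixed epoch budget keeps
runs deterministic and avoids carving a validation split out of already
small folds. Ties at exactly 0.5 predicted probability resolve to
"abnormal", the safer clinical default.

## The phantom generator

`generate_phantom()` composes, in order: a half-ellipse breast on a dark
background with a smooth skin-line taper (intensity falls off over the
outer 12% of the ellipse radius, as compressed tissue thins — a hard step
would dominate co-occurrence statistics and drown texture signals); a
smooth parenchymal field (correlation length 12 px) plus brighter
glandular patches; an optional pectoral wedge anchored at the top-left
image corner; for the abnormal class a flat-topped radially decaying mass
(contrast delta = 60 by default, radius 22-40 px) carrying finer internal
texture (correlation length 3 px, amplitude `0.5 * delta`), six radial
spicules and eight 2 x 2 microcalcification specks (`+0.5 * delta` over
their surround); Gaussian pixel noise (SD 8); and a detector-saturation
shoulder at 235 before noise, so every phantom spans the same raw dynamic
range and contrast stretching has a stable gain across the corpus.

Three structural choices matter for interpretation:

* every random component that distinguishes the classes scales with the
  lesion contrast, and class-independent draws (fields, noise) happen
  before any lesion geometry — so at `delta = 0` with no spicules or
  calcifications, normal and abnormal phantoms with the same seed are
  *bitwise identical*, giving exact null-effect runs;
* lesion centres are sampled away from the skin line, the frame edge, and
  saturated glandular islands, where an additive bump would clip and
  become invisible — the generator's contract is that the abnormal class
  differs in intensity, run-length and co-occurrence structure, with the
  separation growing in `delta`;
* per-image seeds are derived by integer mixing from the dataset seed and
  image index, so any subset regenerates identically regardless of order.

The phantoms emulate class-discriminating texture at trivially known
ground truth. They do not emulate the anatomy of real mammograms —
ductal structure, tissue-type heterogeneity, view geometry, scanner
artefacts — so passing phantom studies demonstrates that the pipeline's
machinery works and is internally consistent, not that its clinical
accuracy on MIAS-like data is any particular number.

## Evaluation

`confusion()` counts with "abnormal" as the positive class;
`compute_metrics()` reports accuracy, sensitivity `TP/(TP+FN)`,
specificity, precision and F1. Sensitivity uses the standard denominator
(the alternative printed form `TP/(TP+TN)` contradicts both convention and
its own surrounding usage), precision is the standard `TP/(TP+FP)`, and
zero-denominator ratios report 0 with a warning so degenerate folds do not
abort a cross-validation.

`stratified_kfold()` deals each class round-robin after a seeded shuffle,
so per-fold class counts deviate from proportionality by at most one.
`crossvalidate()` fits the feature scaler and the model on training folds
only. The label-permutation null and the ablation arms use a 3-epoch
training budget: the chance-band and weak-dominance properties they check
do not depend on convergence, and the saved time funds the converged main
run. The study sizes — 50 phantoms per class, 5 folds, test-scale
channel widths — are the package's reference conditions throughout tests
and the acceptance script.

`compare_feature_groups()` reports class means with Welch or seeded
label-permutation p-values; the permutation path is validated against
exhaustive enumeration on a 4-vs-4 split and for type-I calibration under
a true null. `run_ablation()` toggles the five named stages (contrast,
median, shearlet, otsu, canny) over identical folds.

## Known limitations

* The shearlet system is band-limited (periodic boundary handling);
  compactly supported shearlets are out of scope.
* The pectoral-wedge heuristic assumes a corner-anchored bright triangle
  and is off by default; oblique-view pectoral shadows with weak contrast
  will be missed.
* The ROI on phantom-like images is effectively the breast bounding box;
  descriptors are therefore breast-global statistics rather than
  lesion-local ones, and the classifier compensates through fusion.
* Full-width (channel_scale 1) training is supported but computationally
  serious on CPU; the package's own studies run at 0.125.
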