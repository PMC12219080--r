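# mammotex

Texture-based mammogram analysis with a hybrid BiLSTM-CNN classifier.

Screening mammograms are low-contrast, noisy images in which early masses
and microcalcifications are easy to miss. Computer-aided-diagnosis pipelines
attack this with three ingredients: image enhancement that sharpens lesion
boundaries, segmentation that localises a region of interest, and
classification that combines handcrafted texture statistics with learned
representations. mammotex implements that pipeline end to end for two-class
(normal vs. abnormal) decisions, for researchers who want a fully
inspectable, reproducible R implementation:

* **IO** — PGM (`P2`/`P5`) and PNG grayscale images, and the MIAS-style
  plain-text annotation format (`read_pgm()`, `parse_mias_info()`).
* **Preprocessing** — bilinear resize to 224 x 224, contrast stretching,
  3 x 3 median filtering, and enhancement in a cone-adapted band-limited
  shearlet frame whose squared filters form an exact partition of unity, so
  reconstruction is exact and the gain step is fully testable
  (`build_shearlet_system()`, `shearlet_enhance()`).
* **Segmentation** — breast cropping with optional pectoral-wedge removal,
  *improved Otsu* thresholding in which each pixel weights the histogram by
  `1 + alpha * localvar/max(localvar)` (classical Otsu at `alpha = 0`), and
  Canny edge refinement with thresholds at 0.1/0.3 of the peak gradient
  magnitude; the union localises the ROI (`improved_otsu_threshold()`,
  `canny_edges()`, `extract_roi()`).
* **Hybrid features** — a canonical 49-vector: 5 first-order histogram
  statistics, 6 gray-level co-occurrence descriptors (energy, contrast
  `sum_n n^2 P(|i-j|=n)`, entropy, homogeneity, correlation, shade) over 4
  directions, and 5 gray-level run-length descriptors (SRE
  `(1/Nr) sum R(i,j)/j^2`, LRE, LGRE, HGRE, GLN) over 4 directions
  (`assemble_hybrid()`).
* **Classifier** — a compiled CNN (five convolution blocks, 4x4/2 max
  pooling, the printed 224-150-144-71-65-31-25-11-7-2 spatial ladder)
  whose final maps unroll into a length-256 sequence feeding a
  bidirectional LSTM (64 units per direction), with optional fusion of the
  z-normalised 49-vector before the dense softmax head; deterministic
  training with Adam (`bilstm_cnn_spec()`, `train_model()`, `predict()`).
* **Evaluation** — confusion-matrix metrics, stratified k-fold
  cross-validation with per-fold mean +- SD, per-feature class comparisons
  (Welch / permutation), and a preprocessing ablation grid
  (`crossvalidate()`, `compare_feature_groups()`, `run_ablation()`).
* **Phantoms** — a seeded generator of mammogram-like images (breast
  ellipse, parenchymal and glandular texture, optional pectoral wedge,
  masses with spicules and microcalcifications at controllable contrast)
  with exact ground truth, so the whole pipeline runs and is tested without
  any external download (`generate_dataset()`).

## Worked example

Simulate a small labelled corpus, extract hybrid features, and
cross-validate the fused classifier at test-scale channel widths:

```r
library(mammotex)

gen <- generate_dataset(phantom_params(), n_per_class = 50, seed = 0)
gen$dataset
#> <mammo_dataset> 100 images (50 normal, 50 abnormal)

cfg <- pipeline_config(
  train = list(epochs = 10L, learning_rate = 0.002, batch_size = 4L))
ft <- feature_table(gen$dataset, cfg)           # 100 x 51 tibble
cv <- crossvalidate(gen$dataset, cfg, k = 5, seed = 0, features = ft)
cv$per_fold$accuracy
#> [1] 1.00 0.95 0.85 0.85 0.90
print(cv)
#> <cv_result> 5-fold stratified CV (seed 0)
#>   mean accuracy 0.910 +- 0.065
```

Each fold trains on 80 phantoms (feature scaling fitted on the training
fold only) and scores the held-out 20; the mean accuracy of 0.91 says the
fused model separates the two phantom classes well above chance, while a
label-permutation rerun of the same protocol stays near 0.5. Per-feature
class separation works the same way:

```r
cmp <- compare_feature_groups(ft[, c("glcm_contrast_d0", "label")],
                              ft$label, method = "permutation",
                              n_perm = 2000, seed = 1)
cmp$p_value
#> [1] 5e-04
```

The lesion class carries systematically higher co-occurrence contrast —
the signature its finer internal texture is designed to leave.

Single images go through the same stages explicitly:

```r
ph  <- generate_phantom(phantom_params(), "abnormal", seed = 1)
pre <- preprocess_image(ph$image)               # resize/stretch/median/shearlet
ot  <- improved_otsu_threshold(pre)
ed  <- canny_edges(pre)
roi <- extract_roi(pre, ot$mask, ed)
fv  <- assemble_hybrid(roi$image)               # named 49-vector
```

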