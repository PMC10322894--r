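# morphovae

Landmark-free geometric morphometrics for three-dimensional bone-like
shapes (the motivating case is the mammalian mandible), built around a
supervised convolutional variational autoencoder.

Classical morphometrics needs expert-placed anatomical landmarks, which
do not exist across distant taxa and lose information however many you
pick. `morphovae` instead works on the shape itself: a binary voxel
volume is oriented into a canonical anatomical frame, split at the
sagittal plane into two mirrored half-specimens, and reduced to a triplet
of 128×128 binary silhouette projections (x/y/z views). A convolutional
VAE whose 3-D latent ζ also feeds a single-layer softmax classifier is
trained on

    E_total = (1 − α) · (E_Rec + E_Reg) + α · E_C,        α = 0.1

with per-pixel binary cross-entropy `E_Rec`, the closed-form KL
divergence of `N(μ, σ)` from `N(0, I)` as `E_Reg`, and the label
cross-entropy `E_C`. The classifier term makes ζ a *morphological
feature* in which labelled groups (families, genera, …) form separated
clusters. Everything — stride-2 convolutions, backprop, RMSprop/Adam/SGD —
is implemented in R/C++ with no deep-learning framework; gradients are
verified against finite differences in the test suite.

On top of the model sit the evaluation tools of this approach:

* `compute_csi()` / `davies_bouldin()` — pairwise cluster separation
  index `(δ_i + δ_j)/Δ_ij` (RMS dispersions; < 1 means separated) and its
  max-then-mean aggregation (Davies–Bouldin with p = q = 2);
* `svm_latent_accuracy()` — RBF-kernel SVM readout (C = 1, tol = 0.001,
  γ = 1/latent-dim), with `pca_baseline()` and an α = 0 run as the
  unsupervised baselines;
* `reclassification_accuracy()` — classification of re-encoded
  reconstructions, a proxy for how much morphology the latent preserves;
* `latent_pca_grid()` — decoded image grids on the PC1–PC2 plane of the
  latent space (PC3 = 0), the generative visualization;
* `score_cam()` / `direction_ablation()` — Score-CAM saliency maps and
  blank-channel ablations explaining which image regions and projection
  directions drive classification;
* `crop_volume()` / `crop_response_curve()` — the missing-segment
  experiment: crop a fraction of the object's extent, re-project, and
  trace reconstruction loss and accuracy versus crop rate;
* `generate_shape_volume()` / `shape_presets()` — a synthetic generator
  (body ellipsoid + three class-distinct bony "processes", 0.5–2.5×
  size jitter) so the entire pipeline runs and is tested without any
  external CT data.

See `vignettes/morphovae-methods.Rmd` for the model, its assumptions,
all numerical choices, and known limitations.

## Worked example

```r
library(morphovae)

# synthetic dataset: 3 classes x 20 specimens -> 120 half-specimens
ds <- synthetic_morphovae_dataset("separable", n_classes = 3,
                                  n_per_class = 20, seed = 42)
split <- make_splits(ds, seed = 42)

cfg <- morphovae_config(n_classes = 3, alpha = 0.1,
                        encoder_filters = c(8, 8, 16, 16, 32),
                        decoder_filters = c(32, 16, 16, 8, 8),
                        batch_size = 16, learning_rate = 2e-3,
                        epochs = 40, seed = 42)
model <- train_model(ds, cfg, split)

te <- which(ds$parent_id %in% split$test_ids)
tr <- which(ds$parent_id %in% split$train_ids)
enc <- function(i) t(encode(model, ds$triplets[, , , i, drop = FALSE],
                            mode = "deterministic")$mu)
z_te <- enc(te); z_tr <- enc(tr)

davies_bouldin(compute_csi(z_te, ds$labels[te]))
#> [1] 0.317109
svm_latent_accuracy(z_tr, ds$labels[tr], z_te, ds$labels[te])
#> [1] 0.95
reclassification_accuracy(model, ds$triplets[, , , te, drop = FALSE],
                          ds$labels[te])
#>      original_acc reconstructed_acc
#>                 1                 1
```

A Davies–Bouldin score of 0.32 (≪ 1) says the three shape classes form
well-separated clusters in the 3-D latent; the SVM reads the class off
the held-out latents at 95%, and reconstructions classify exactly as
well as the originals, i.e. the 3 numbers that summarize each shape
retain its class-relevant morphology. (Values printed by this code with these
seeds; class geometry differs by condylar-process angle, 25°–70°.)

## Command line

```sh
Rscript inst/cli/morphovae.R synth --preset separable --classes 3 --n 20 --seed 7 --out data/
Rscript inst/cli/morphovae.R train --data data/ --out run/ --epochs 40
Rscript inst/cli/morphovae.R eval  --run run/ --data data/ --out metrics.json
Rscript inst/cli/morphovae.R crop-curve --run run/ --data data/ --axis vertical --out curve.csv
```

## Data formats

Voxel volumes are plain-text run-length files (JSON header + RLE body,
`write_voxel_volume()`); datasets are described by a CSV manifest with
`specimen_id`, `label` and landmark coordinate columns (`condyle_left_*`,
`condyle_right_*`, `tip_*`, `angular_*`; physical x/y/z, 0-based voxel
units). Model checkpoints are JSON (`save_model()`/`load_model()`).
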