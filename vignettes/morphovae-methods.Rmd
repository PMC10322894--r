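---
title: "Landmark-free morphometrics with a supervised convolutional VAE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free morphometrics with a supervised convolutional VAE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphovae)
```

## The problem

Classical geometric morphometrics quantifies biological shape through the
coordinates of homologous anatomical landmarks. That requires expert
annotation, breaks down between distant taxa or developmental stages where
homologous points cannot be defined, and loses information when landmarks
are too few or too many. `morphovae` implements a landmark-free
alternative for three-dimensional bone-like objects (the motivating system
is the mammalian mandible): shapes enter as binary voxel volumes, are
reduced to silhouette images, and a neural network learns a
three-dimensional morphological feature in which labelled groups (e.g.
taxonomic families) separate.

## Preprocessing: from voxels to projection triplets

A specimen is a binary occupancy grid with three anatomical landmarks: the
two medial tips of the condylar heads and the mandible tip (plus the
angular-process tip used for size normalization).

1. **Canonical orientation.** The volume is rigidly rotated so the
   condylar-midpoint-to-tip line is parallel to +y, the condyle-to-condyle
   axis parallel to x, and the teeth-bearing base faces -z. Resampling is
   trilinear with a 0.5 threshold; a volume already canonical is returned
   voxelwise unchanged, and the occupancy count is checked to stay within
   2%.
2. **Split and mirror.** Mandibles are left-right symmetric, so each
   volume is split at the sagittal plane through the tip (0-based,
   half-open windows; `k0 = round(tip_x)`) and the right half is mirrored,
   doubling the dataset while presenting a single chirality. Both halves
   keep the parent specimen id; the split logic in `make_splits()` uses it
   to prevent train/test leakage of the same bone.
3. **Silhouette projection.** Each half is projected along x, y and z;
   a pixel is on iff any occupied voxel lies on its ray. Silhouettes (not
   depth maps) were chosen because the model consumes binary images in
   [0, 1].
4. **Size normalization and rasterization.** All three images are scaled
   by one factor so that the angular-process-to-tip distance becomes
   `target_length_px`, bilinearly interpolated, re-binarized at 0.5 and
   centered on a 128 x 128 canvas. Real specimens span roughly a
   five-fold size range; this step removes that nuisance variation.

Numerical choices: bilinear-then-threshold gives deterministic,
antialias-free binarization. Placement uses the occupied bounding-box
center of each image — the landmark segment lives in only one projection
plane, so segment-midpoint centering would be undefined for the other two
images; any fixed convention works because the network always sees the
same placement. `target_length_px` is exposed as configuration and
defaults to 52 px: the synthetic shapes span about 2.2x their landmark
segment, so 52 px keeps the whole silhouette on the canvas across the
full size-jitter range (a value like 88 px would suit real mandibles,
whose landmark segment is nearly the full bone length).

## The model

The network is a convolutional variational autoencoder with a classifier
head, implemented from first principles (im2col/shift-GEMM convolutions
in C++, hand-derived backpropagation — no deep-learning framework exists
in this stack; the gradients are verified against finite differences in
the test suite).

* **Input**: the three 128 x 128 projections enter as the 3 channels of
  one image.
* **Encoder**: stride-2 3 x 3 convolutions (default five layers, filters
  128, 128, 32, 32, 64, ReLU), then two affine heads give the mean
  $\mu$ and log-variance of a diagonal Gaussian over the latent
  $\zeta \in \mathbb{R}^3$; training samples
  $\zeta = \mu + \sigma \odot \varepsilon$.
* **Decoder**: an affine map to a 4 x 4 seed followed by five
  (upsample x2 + 3 x 3 convolution) blocks (filters 64, 32, 32, 128,
  128), with a logistic output layer so pixel values stay strictly in
  (0, 1).
* **Classifier**: a single affine layer plus softmax on $\zeta$ — the
  supervised signal that shapes the latent space.

The training objective is

$$E_\mathrm{total} = (1-\alpha)\,E_\mathrm{VAE} + \alpha\,E_C,\qquad
  E_\mathrm{VAE} = E_\mathrm{Rec} + E_\mathrm{Reg},$$

with per-pixel binary cross-entropy $E_\mathrm{Rec}$ (decoder outputs
clipped to $[10^{-7}, 1-10^{-7}]$ inside the logarithms), the closed-form
KL divergence of $N(\mu,\sigma)$ from the standard-normal prior
$E_\mathrm{Reg} = \tfrac12\sum_k (\mu_k^2 + \sigma_k^2 - \log\sigma_k^2 - 1)$,
and the label cross-entropy scaled by $1/n_\mathrm{classes}$ as $E_C$.
$\alpha = 0.1$ is the default operating point; `select_alpha()` reproduces
its selection by cross-validation (the smallest $\alpha$ whose $E_C$ is
near its minimum while $E_\mathrm{VAE}$ barely exceeds the $\alpha = 0$
baseline). At $\alpha = 0$ the classifier receives no gradient and the
model reduces to a plain VAE — which doubles as the unsupervised baseline.

**Loss scales.** The components above are *reported* in the textbook
normalization (per-pixel mean for $E_\mathrm{Rec}$, per-class mean for
$E_C$, raw KL sum for $E_\mathrm{Reg}$). Trained literally at that
scale the objective fails twice over. First, it is a $\beta$-VAE with
$\beta \approx$ the pixel count ($\sim 5\times10^4$): one nat of KL
outweighs any reconstruction improvement the latent can buy, the
posterior collapses to the prior and the decoder emits the dataset-mean
image — we verified exactly this on the synthetic fixtures (latent
standard deviations $\sim 0.005$, dead classifier) at several learning
rates and step budgets. Second, even without collapse an $O(1)$
classification term weighted by $\alpha = 0.1$ is invisible next to a
pixel-summed reconstruction, so the supervised signal could never shape
the latent — yet visible supervised shaping (and a visible
$E_C$/$E_\mathrm{VAE}$ trade-off across $\alpha$) is the model's central
phenomenon. Both observations pin down the working objective: the two
cross-entropies enter at their *sum-over-units* scale. The training
objective therefore multiplies $E_\mathrm{Rec}$ by `recon_loss_scale`
and $E_C$ by `class_loss_scale` (both defaulting to the pixel count
$128\times128\times3$, making the $\alpha$-weighted terms commensurate;
setting both to 1 recovers the literal normalized objective for anyone
who wants to observe the collapse). All *reported* loss components,
histories and loss-identity assertions remain in the printed
normalization, and best-epoch selection uses the optimized objective
(`val_objective`) — under the printed normalization the growing KL of an
informative latent would otherwise select a collapsed early epoch.

Design notes where the original description is open:

* The three projections enter as channels of a single image — the
  simplest layout that treats the triplet as one network input.
* Some statements of the reconstruction loss carry a stray minus sign
  that would make the loss unbounded below; standard binary
  cross-entropy is implemented.
* The hidden decoder activation is ReLU with a logistic output layer; a
  fully logistic decoder (an alternative reading of the architecture) is
  available via `decoder_activation = "sigmoid"`.
* Whether the encoder emits $\sigma$ or $\log\sigma^2$ is unstated; the
  log-variance parameterization is used (clamped to $[-15, 15]$ for
  numerical safety).
* All randomness — initialization, $\varepsilon$ draws, shuffling — derives
  from the single `seed` in `morphovae_config()`; two runs with the same
  configuration are bitwise identical, and deterministic evaluation mode
  ($\zeta=\mu$) makes encode/decode/classify pure functions.

## Training protocol

`make_splits()` holds out one third of the *specimens* as test data; the
remainder splits 75/25 into training and validation. Stratification uses
largest-remainder rounding so per-label proportions match the dataset
within one specimen, mirrored halves always travel with their parent, and
labels with a single specimen fall back to training with a warning.
Training runs a fixed number of epochs (default 100, no early stopping);
the checkpoint kept is the epoch with the lowest validation
$E_\mathrm{total}$. The loss identities are asserted on every batch.
`tune_hyperparameters()` provides the budgeted random search over the
standard search ranges (1-5 layers, 16-128 filters, ReLU/sigmoid/tanh,
SGD/Adam/RMSprop); `sweep_latent_dim()` reproduces the latent-dimension
sweep that motivated the default of 3.

## Evaluation suite

* **Cluster separation.** For labelled latent points,
  $\mathrm{CSI}_{ij} = (\delta_i + \delta_j)/\Delta_{ij}$ with RMS
  dispersions $\delta$ and centroid distances $\Delta$; values below 1
  indicate separation. `davies_bouldin()` aggregates by
  $\frac1k\sum_i \max_{j\ne i}\mathrm{CSI}_{ij}$ (the Davies-Bouldin
  index with $p=q=2$). Coincident centroids report `Inf` with a warning
  rather than an error so the failure is detectable downstream. Note that
  common reference implementations of Davies-Bouldin use *mean* rather
  than RMS dispersion; `compute_csi(..., dispersion = "mean")` matches
  that convention and is tested against a value frozen from one such
  implementation.
* **SVM readout.** An RBF-kernel C-SVM (simplified SMO, one-vs-one
  voting) with the fixed protocol settings C = 1, tolerance 0.001,
  kernel coefficient 1/latent-dim. Latent points use deterministic
  encoding ($\zeta = \mu$) throughout the evaluation suite.
* **Baselines.** `pca_baseline()` flattens triplets to pixel vectors and
  keeps the top 3 components (mean-centered, unscaled). The full triplet
  (49,152 pixels) is flattened, so the baseline sees exactly the model's
  input; a per-image 16,384-dim variant would see one projection only.
  The plain-VAE baseline is an $\alpha = 0$ run of the same code.
* **Reconstruction quality** is scored by re-classification: the
  reconstruction is re-encoded and classified, and its accuracy compared
  with the original's.
* **Latent grid.** `latent_pca_grid()` decodes a grid on the PC1-PC2
  plane of the latent points at PC3 = 0 (grid extent: data bounding box
  expanded 10%) and classifies each node; data points carry their |PC3|
  distance for size-coded plotting.
* **Score-CAM.** Activation maps of the encoder layer with the 8 x 8
  output (the 4th of five stride-2 layers from 128 px) are bilinearly
  upsampled, min-max normalized, used to mask the input, and weighted by
  the masked input's softmax probability for the explained label — plain
  Score-CAM, no baseline subtraction, probabilities not logits. Per-class
  maps are means of per-sample maps. Constant activation maps contribute
  zero with a warning.
* **Occlusion.** `crop_volume()` removes a slab whose thickness is
  `round(rate * occupied_extent)` — rates are relative to the object, not
  the canvas. Vertical crops remove the teeth-side (low-z) slab, mimicking
  missing alveolar bone; horizontal crops remove the anterior tip.
  Cropped volumes are re-projected with the *stored* canvas transform of
  their uncropped parent: re-normalizing would rescale the remaining
  anatomy and hide exactly the defect the experiment measures.
  `crop_response_curve()` scores each cropped reconstruction against the
  *original* triplet and classifies the re-encoded reconstruction
  (classification of the cropped input's latent is available via
  `classify_on = "input"`).

## The synthetic-shape generator

No real CT data ship with the package; `generate_shape_volume()` builds
class-labelled stand-ins: a body ellipsoid carrying three rod-like
processes per side (stand-ins for the coronoid, condylar and angular
processes) whose elevation angles and lengths are drawn from
class-specific distributions. The `separable` preset spreads condylar
angle means 25-70 degrees with a 3-degree within-class standard deviation
(> 3 sd between classes); `hard` overlaps them (means 40-50, sd 4). A
global size-jitter factor (default 0.5-2.5x, i.e. a five-fold spread like
real specimens) exercises the size normalization. Shapes are aligned to
the canonical pose *analytically* — the primitives are rotated before
voxelization — so generated volumes are exactly canonical and carry exact
landmarks. Connectivity is guaranteed by anchoring processes inside the
body; a 6-connectivity check with regeneration backs this up (verified for
the first specimen of each class by default; the full check is O(volume x
diameter) and available with `check_connectivity = "all"`).

The `quadrant` preset builds the saliency/ablation fixture: identical
bodies and connector across classes, with the only class-informative
structure a bar pattern (rising diagonal / falling diagonal / cross)
extruded along x inside one yz-plane box. Every pattern touches every row
and column of its box, so the y and z projections are identical rectangles
across classes — provably uninformative — while the x projection shows the
pattern inside one canvas quadrant. The pattern is deliberately larger
than the body so that localized saliency is measurable against the shared
background.

What a green test on synthetic data does establish: the pipeline's
operations are correct (exact oracles), the optimization descends, the
supervised latent separates classes that differ in process geometry, and
the saliency/ablation/occlusion analyses recover structure placed into the
fixtures by construction. What it does not establish: performance on real
mandible CTs (anatomical detail, scanning artifacts, within-family
variation are not emulated), nor any reference results that belong to real CT datasets this
package does not ship.

## Known limitations

* The convolution stack is CPU-only and sized for hundreds, not millions,
  of images.
* With few optimizer steps (small datasets, few epochs) the raw KL sum
  transiently inflates while the classification term reorganizes the
  latent, before re-equilibrating as $E_C$ saturates; monitor the
  optimized VAE loss (`recon_loss_scale * E_Rec + E_Reg`, as
  `select_alpha()` reports) rather than the per-pixel-normalized
  `e_vae`, which is dominated by that transient.
* Automatic anatomical landmark detection is out of scope; landmarks are
  supplied as manifest columns.
* Voxel containers are plain-text run-length encodings plus CSV manifests;
  no binary voxel format has an offline reader in the supported stack.
* The SMO-based SVM is exact enough for the small latent datasets it
  serves but is not a general-purpose SVM implementation.
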