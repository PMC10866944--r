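---
title: "Hybrid CNN-Transformer glioma segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CNN-Transformer glioma segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliomaseg` implements a complete 2D multimodal glioma-segmentation
pipeline: preprocessing of skull-stripped BraTS-layout NIfTI cases, a
hybrid convolutional/vision-transformer encoder–decoder trained with a
generalized-dice + cross-entropy objective under case-level k-fold
cross-validation, STAPLE fusion of the fold models, DSC/HD95 region
evaluation, and a post hoc Grad-CAM explanation generator. This vignette
records the model assumptions, the tunable parameters, and the design
decisions taken where the design was genuinely open.

## Data model and preprocessing

A case is four co-registered, skull-stripped 3D channels (T1, T1Gd, T2,
FLAIR) at 1 mm isotropic resolution with an integer label volume over
{0, 1, 2, 4}. Every volume is reoriented to one canonical orientation
("LAS") at load, so axial slices are always the third array axis.

Preprocessing follows a fixed chain:

1. **Brain-FOV zeroing.** The brain mask is the union of nonzero voxels
   across channels, minus 6-connected components smaller than 1 % of the
   largest. Skull-stripped inputs already have zero background, so the
   operation is idempotent; the component filter only guards against
   stray nonzero speckles.
2. **Z-score per volume per channel** over brain voxels only, with the
   *population* standard-deviation convention (fixed so exact-value
   tests are well defined; the sample convention would be equally
   defensible). Whether the statistics should include background voxels
   is not determined by the training recipe we follow; brain-only was
   chosen because the background is forced to exactly 0 first, and
   including it would dilute the statistics by a factor tied to the
   brain/FOV ratio rather than to the anatomy. A constant channel falls
   back to unit standard deviation and raises a flag.
3. **Center crop** of the geometric array center (not the brain-mask
   centroid) to `crop_size` (192×192 at full scale), zero-padding
   smaller inputs first; per-axis offsets (negative = padding) are
   recorded so predictions can be mapped back exactly.
4. **Axial slicing** into H×W×4 slice pairs. For training, slices with
   fewer than `min_brain_fraction` (default 1 %) brain pixels are
   dropped — empty slices waste batches; for inference all slices are
   used and reassembled through the recorded crop, so the output volume
   has the original geometry bit-exactly.

## Network

The encoder has four double-conv blocks `[conv3×3 → BN → ReLU] ×2`
(widths K, 2K, 4K, 8K; K = 32 by default) separated by 2×2 max-pooling,
giving an H/8 bottleneck — at 192×192 input, a 24×24×256 feature map.
Bottleneck features are embedded as tokens (patch size P = 1 by default:
one token per spatial position; a learned linear projection plus learned
1D positional embeddings) and passed through L = 4 pre-norm transformer
blocks (8 heads, embed dim 256, MLP dim 1024, GELU): layer norm before
both the multi-head self-attention and the MLP, residual connections
around each. Feature restoration reshapes tokens back to the spatial
grid and applies a 1×1 conv back to the encoder width. The decoder is
symmetric: a double-conv block at bottleneck resolution, then three
stages of 2×2 transposed convolution, concatenation with the
matching-resolution encoder skip, and a double-conv block, ending in a
1×1 conv to 4 classes and a per-pixel softmax. This reading — four
encoder and four decoder conv blocks, eight in total — pairs a full-
resolution decoder block count with three poolings; the transformer
hyperparameters (L, heads, dims, P), which the architecture description
leaves open, are config-exposed with ViT-conventional defaults.

Weight initialization: He-normal for convolutions, truncated normal
(sd 0.02) for transformer projections and positional embeddings.
Normalization: batch norm only in conv blocks, layer norm only in the
transformer. Up-convolutions are transposed convolutions (the literal
reading of "2×2 up convolution") rather than upsample-then-conv.

Everything — convolution, BN, pooling, attention, LN, GELU, transposed
convolution — is implemented with explicit forward and backward passes
(im2col + BLAS GEMM in C++ for the convolutions). The full-network
gradient is validated against central finite differences in the tests;
this hand-rolled engine is what makes a trained, differentiable model
available to the Grad-CAM generator without any external framework.

## Objective

`L = L_GD + L_CE`, computed per batch with class sums pooled over the
batch (pooling stabilizes the adaptive weights for rare classes).
Generalized dice uses `W_c = 1/(Σ y_c)²`; a class absent from the batch
gets weight 0 — the bounded-limit guard used by reference
implementations. An additive ε = 1e-5 smooths numerator and denominator,
read as the usual smoothing role of the unspecified "regularization
parameter". Cross-entropy clips probabilities at 1e-7 inside the log.
The denominator of the dice term is interpreted as `Σ_c W_c (Σ_n y +
Σ_n s)` — the standard generalized-dice form — where the printed
expression is typographically ambiguous.

## Training

Momentum SGD (0.9), constant learning rate, per-epoch reshuffling, all
retained slices visited once per epoch, augmentation applied on the fly
per sample. Defaults follow the published recipe (lr 8e-3, batch 16,
250 epochs, 5 folds). Cross-validation splits are case-level only, so no
validation case ever contributes a training slice. The best checkpoint
is selected by the mean validation dice over ET, TC and WT (no selection
rule is published; selecting on whole-tumor dice alone was observed to
keep checkpoints whose sub-labels are still degenerate, so the region
mean is used). Seeds fan out from one
global seed via stable integer hashing (per fold, epoch, batch, sample),
which makes runs bit-reproducible.

**Desk-scale preset.** The shipped `defaultRunConfig()` trains a shrunk
network (K = 8, L = 1, 96×96 slices) on five synthetic phantoms for
20 epochs with batch 4 and lr 0.07. The larger step size and smaller
batch are deliberate: this regime takes roughly three orders of
magnitude fewer SGD steps than a full BraTS training run, and at the
published learning rate the optimizer is still in the
all-background regime when the step budget ends (class imbalance ~97 %
background; the generalized-dice gradient through a collapsed softmax
cannot recover quickly). With the preset, validation WT dice typically reaches
0.9–0.99 in a few CPU-minutes per fold. Problem sizes used by the tests
and the acceptance script — 5 cases of 96×96×32, two folds, 20 epochs —
were chosen as the smallest configuration that exercises every pipeline
stage while leaving the planted effects clearly measurable.

## Augmentation

Spatial transforms (in-plane shift, flips, rotation up to 20° with
random sign, zoom within ±20 %) are applied identically to image
(bilinear) and label (nearest neighbor); intensity transforms
(multiplicative brightness within ±20 %, Gaussian noise sd 0.01 in
normalized units) to the image only. Out-of-frame regions get the
background value 0. Open readings resolved here: "0 to 20 degrees" is
taken as a magnitude with uniform random sign (one-sided rotation would
be anisotropic for no stated reason); "adaptive zooming" as uniform
random zoom in ±20 %; brightness "deviation of 20 %" as a
multiplicative factor U(0.8, 1.2) on z-scored intensities (an additive
shift is the plausible alternative); the shift range, for which no value
is published, defaults to 10 % of the image size.

## STAPLE fusion

The fold models' hard label volumes are fused by classic binary STAPLE:
EM alternates posterior estimation of the latent true segmentation with
per-rater sensitivity/specificity updates, initialized at
p = q = 0.99999, scalar prior = mean rater-positive fraction, tolerance
1e-7 on Σ|Δp|+|Δq|, cap 100 iterations. Computation is restricted to the
bounding box of the rater-positive union (identical result, smaller
problem). No multi-category STAPLE variant is specified anywhere we
follow, so the multi-label wrapper is a design choice with two modes.
The default fuses the *nested evaluation regions*: binary STAPLE on WT,
TC and ET masks, posteriors thresholded at 0.5, nesting enforced by
intersection, labels reconstructed (ET→4, TC∖ET→1, WT∖TC→2). The
alternative (`mode = "labels"`) runs one-vs-rest per raw label and
assigns each voxel the label with the highest posterior if it beats the
background posterior, ties broken by the fixed priority 4 > 1 > 2
(enhancing tumor is the costliest to miss). Region fusion is the default
because it is robust at small rater counts: with two fold models that
agree a voxel is tumor but disagree on its sub-label, one-vs-rest fusion
sends the disputed voxel to background — in a measured two-fold phantom
run this collapsed fused whole-tumor dice from 0.99 to 0.58, while
region fusion kept 0.99 with tumor-core and enhancing dice above 0.9.
With exactly two near-unanimous
raters the EM parameters creep toward the boundary slower than the
tolerance; the run then stops at the cap with `converged = FALSE` and a
warning — the posteriors are still well-formed, and fused outputs are
unaffected in practice. Whether hard labels or soft probabilities were
fused in the work we follow is unstated; hard labels are used (soft
fusion is a non-goal).

## Metrics

DSC = 2|P∩T|/(|P|+|T|), with the both-empty convention 1. HD95 uses
surface voxels (mask voxels with a 6-neighbor outside) and pools the
bidirectional nearest-neighbor surface distances before taking the 95th
percentile (`hd95_mode = "pooled"`); the BraTS-tooling convention (max
of directed 95th percentiles) is available as `"max_directed"`. If
exactly one mask is empty the configurable sentinel (default: image
diagonal in mm) is returned; two empty masks give 0.

## Explanation generator

Grad-CAM treats the dense segmentation head like a classifier score:
`y^c` is the sum of class-c scores over a pixel set — by default the
pixels predicted as c (falling back to all pixels when the class is
absent), with "all pixels" and ROI-mask modes exposed, over logits or
softmax. The scalar choice matters and no published definition pins it
down for dense prediction, hence the explicit `classScoreSpec`. The
channel weights are the spatial means of ∂y^c/∂A at the chosen tagged
layer, the map is ReLU of the weighted activation sum, bilinearly
upsampled to the input grid and min-max normalized (an all-zero map is
kept all-zero and flagged rather than divided by zero). Explanations
never modify weights. The modality-ablation experiment zeroes channels
at inference (zero is exactly the background value after z-scoring);
both keep-only and leave-one-out directions are reported. Ablation by
retraining is out of scope.

## The phantom generator

Phantoms emulate the BraTS layout at reduced scale: an ellipsoidal brain
(gray-matter shell, white-matter interior, semi-axes 38×38×14 voxels in
a 96×96×32 grid) with a nested spherical tumor — necrotic core (label 1,
r ≤ 4), enhancing rim (label 4, 4 < r ≤ 7), edema (label 2,
7 < r ≤ 10) — plus per-voxel Gaussian noise (sd 0.04 in intensity units
where tissue means span [0.15, 0.95]) and exact-zero background. The
contrast table plants the radiological signs the attribution experiment
must recover: edema bright on FLAIR/T2 but *identical to white matter on
T1/T1Gd* (so only FLAIR/T2 can reveal it), enhancing rim brightest on
T1Gd, necrotic core darkest on T1Gd. Tumor position jitters by up to
±3 voxels in-plane (±1 axially and in radius, keeping the tumor inside
the brain) across a cohort. At the default noise the tissue classes are
separated by ≥ 6 noise standard deviations in 4-channel space, so the
segmentation task is learnable by construction — a nearest-mean
classifier attains WT dice ≥ 0.98 at low noise, which the tests assert.

What phantoms do **not** model: real anatomy and texture, bias fields,
Rician noise, multi-focal or infiltrative growth, inter-rater label
noise, scanner/protocol heterogeneity. Passing the desk-scale tests
therefore demonstrates that the pipeline's machinery (preprocessing,
optimization, fusion, attribution) is correct and self-consistent — not
that the network would reach any particular accuracy on clinical data.

## Numerical choices and degenerate inputs

* Population std in z-score; constant channels fall back to std 1 with
  a flag.
* Loss smoothing ε = 1e-5; probability floor 1e-7; BN/LN eps 1e-5.
* Softmax is computed with the max-subtraction trick; per-pixel sums are
  within 1e-5 of 1 by test.
* Odd-versus-even crop differences round toward the lower offset
  (`floor((n-s)/2)`).
* Empty-mask HD95 sentinels as above; empty label volumes are valid
  predictions everywhere in the pipeline.
* STAPLE tie-break priority 4 > 1 > 2; all-zero rater stacks fuse to an
  all-background volume without running EM.

## Known limitations

* 2D axial slices only; no 3D context beyond slice-wise inference (a 3D
  variant is explicitly future work in the source design).
* The training engine is single-threaded CPU R/Rcpp: correct and
  verifiable, but not fast; full-scale 240×240×155 BraTS training is out
  of reach by design and out of scope.
* STAPLE operates on hard labels; probability-map fusion is not
  implemented.
* The desk-scale preset's optimizer settings are tuned for the phantom
  regime and should not be read as recommendations for clinical-scale
  training, where the published recipe applies.
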