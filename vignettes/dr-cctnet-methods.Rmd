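---
title: "Grading diabetic retinopathy with a compact convolutional transformer"
author: "drcctnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading diabetic retinopathy with a compact convolutional transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drcctnet)
```

## The problem

Diabetic retinopathy (DR) is graded from colour fundus photographs on a
five-point scale: 0 (no DR), 1-3 (mild, moderate and severe
non-proliferative DR) and 4 (proliferative DR). Public fundus collections
are heterogeneous — different cameras, resolutions, compression and
illumination — and heavily imbalanced: healthy eyes dominate, severe
grades are rare. This package implements a complete grading pipeline
built for that setting: a preprocessing chain that removes the black
camera frame and enhances contrast, a rebalancing scheme (random
under-sampling of the majority grades followed by a twelve-transform
augmentation expansion), and a *compact convolutional transformer* (CCT)
classifier small enough to train on 16 x 16 pixel images, where a
conventional deep network would be both slower and hungrier for data.

Because the real multi-source datasets cannot be redistributed, the
package also ships a seeded synthetic fundus generator. All tests and the
worked examples run on synthetic images; what that does and does not
demonstrate is discussed at the end.

## Preprocessing chain

`preprocess_image()` composes six stages, each exposed individually:

1. **Otsu thresholding** (`otsu_mask`): the image's luminance histogram is
   split at the threshold maximizing between-class variance, separating
   the bright retina disc from the black background. A constant image has
   no two classes and is rejected.
2. **Largest-component bounding box** (`largest_contour_bbox`): connected
   components of the binary mask are labelled (via EBImage) and the
   largest by pixel area — the retina disc — gives a tight bounding box.
   Area is used rather than perimeter because it is robust for a single
   quasi-circular disc; ties break by row-major scan order.
3. **ROI crop** (`crop_to_roi`): pixels are copied unmodified; boxes are
   0-based and half-open.
4. **Morphological opening** (`morphological_open`): erosion then dilation
   with a flat 10 x 10 rectangular element, per channel. The dilation uses
   the reflected element (the adjoint pair), which makes the operation a
   true opening — idempotent and anti-extensive — even for an even-sized
   kernel. It removes bright spurs smaller than the kernel.
5. **Non-local means denoising** (`nlm_denoise`): every pixel becomes a
   weighted average of search-window neighbours, the weight a Gaussian in
   the mean squared difference between 7 x 7 patches (search window
   21 x 21, strength h = 3, all configurable). The kernel is implemented
   in C++ with per-offset integral images, so cost is independent of the
   patch size. Windows clip at borders; a constant image is an exact
   fixed point.
6. **CLAHE on luminance** (`clahe_luminance`): the image moves to analog
   YUV (BT.601), the Y plane is equalized tile-by-tile (8 x 8 grid, clip
   limit 0.5) with bilinear interpolation between tile mappings, and the
   result returns to RGB with chrominance untouched. The equalizer is
   implemented in the package: per-tile 256-bin histograms are clipped at
   `limit` times the mean bin count and the excess is redistributed
   uniformly in one pass, which is guaranteed to terminate for any clip
   limit (iterative redistribution schemes need not be, which is why a
   third-party routine was not used).

Numerical conventions: images are H x W x 3 arrays of whole numbers in
[0, 255]; fractional intermediates round half away from zero; grayscale
conversion uses BT.601 luma weights. The stage order is fixed (artifact
removal, then denoising, then enhancement); no reordering flag is
offered.

## Rebalancing and augmentation

Class rebalancing works on a *manifest* (`dr_manifest`), one row per
image with its grade. The under-sampling cap is the truncated mean of the
three smallest class counts (`compute_cap`, auto mode). For the merged
public collections that mean is 2,382, while the published pipeline used
2,384; the default configuration therefore pins `explicit_cap = 2384`
(explicit mode) so the published table is reproduced exactly, and auto
mode documents the honest arithmetic. Only the two grades with the most
images are reduced to the cap — the remaining imbalance is narrowed by
augmentation, not by discarding scarce data.

`expand_manifest()` then multiplies every class by exactly 13: each image
keeps its original and gains one variant per augmentation op. The twelve
ops are two centre zooms (1.2, 1.5), vertical flip, combined
horizontal-vertical flip (a 180-degree rotation), rotations by +90 and
-90 degrees, and six photometric adjustments. The photometric magnitudes
are not dictated by the method, so the package uses mild,
visibility-enhancing defaults — brightness, contrast and colour
(saturation) x 1.2, sharpness x 1.5, gamma 0.8, and seeded per-channel
jitter within +/-10 levels — all configurable through
`augmentation_ops()`. Geometric ops on square inputs are index
operations, hence bit-exact involutions; zooms resample about the centre
and crop back so every variant keeps its input's dimensions.

Whether augmentation should precede or follow the train/validation/test
split is genuinely open (expanding before splitting leaks near-duplicates
across splits). The pipeline's `augment$scope` flag offers both;
`"all"` is the default because the published image counts imply
whole-dataset expansion.

## The classifier

The model (`cct_config`, `dr_cct`) is a compact convolutional
transformer: a small convolutional tokenizer followed by a transformer
encoder and attention pooling, with no class token and no positional
embedding.

- **Tokenizer**: two stages of (conv k x k, stride 1, no bias) -> ReLU ->
  max-pool 3 x 3 / stride 2, with same padding and 64 then 128 filters.
  A 16 x 16 input becomes 16 tokens of width 128, a 32 x 32 input 64
  tokens; the flattening is row-major.
- **Encoder block** (pre-norm residual): `x1 = x + SD(MHA(LN(x)))`,
  `out = x1 + SD(MLP(LN(x1)))`, where MHA has 2 heads of key width 128
  (inner width 256) with an output projection back to 128, the MLP is one
  dense 128 layer with ReLU and dropout, and SD is stochastic depth with
  rate 0.1 (each residual branch is dropped per sample during training
  and rescaled by the keep probability; evaluation is deterministic).
- **Sequence pooling**: a learnable scorer maps each token to a logit; the
  per-sample softmax of those logits weights the tokens into a single
  128-vector. The weights are non-negative and sum to one by
  construction.
- **Head**: a dense 128 -> 5 layer with softmax.

The bias-free tokenizer and the 2 x 128 attention layout are not
arbitrary: they are the unique standard configuration under which the six
published trainable-parameter counts of the architecture family are all
simultaneously exact. `count_parameters()` computes the count
analytically; for the one-block family it reduces to
`8384 k^2 + 150022` for tokenizer kernel `k`, giving 158,406 / 183,558 /
225,478 / 284,166 for k = 1, 2, 3, 4, with each additional MLP dense
layer adding exactly 16,512. Without positional embeddings the count is
independent of the input size, which is what makes the same 225,478-
parameter model runnable at 16, 24, 28 and 32 pixels. The tests verify
the analytic count against a per-tensor enumeration of the instantiated
network across the ablation grid.

```{r params}
count_parameters(cct_config())
count_parameters(cct_config(image_size = 32))
sapply(1:4, function(k) count_parameters(cct_config(conv_kernel = k)))
```

## Training

`dr_cct()` minimizes categorical cross-entropy (four alternative losses
are available) with Adam at learning rate 0.001, batch size 256 and
decoupled weight decay 0.001 — the configuration the ablation studies
selected. Everything stochastic (initialization, data order, dropout,
stochastic depth, splits) derives from explicit seeds, so runs are
reproducible bit-for-bit; with learning rate zero the weights are
bit-identical after an epoch, which the tests assert.

Implementation choices worth stating:

- The forward and reverse passes are written directly in R against BLAS
  matrix multiplies (convolutions as per-offset GEMMs, pooling with
  recorded argmaxes, per-sample attention). Analytic gradients are
  checked against central finite differences in the test suite, in both
  evaluation and training mode.
- Weight decay is decoupled (applied to the weights after the adaptive
  step), since it is configured alongside Adam rather than folded into
  the loss.
- Initialization is Glorot-scaled truncated normal (clipped at two
  standard deviations); layer norms start at identity. Glorot scaling
  matters here: with a fixed small standard deviation the model spends
  many epochs on a uniform-prediction plateau before learning starts.
  No learning-rate schedule, warmup, label smoothing or early stopping
  is used, as none is part of the method.
- Splits (`split_manifest`) are stratified per grade at 70/20/10 with
  largest-remainder rounding, so per-class counts are within one entry of
  the exact fractions.

`reduction_protocol()` implements the robustness experiment: for each
fraction of the training pool (1.0, 0.75, 0.5, 0.25 by default) it
subsamples uniformly (fresh seeded draw per repeat), retrains from
scratch, evaluates on the fixed test split, and reports the mean accuracy
and the max-minus-mean spread over repeats.

## The synthetic fundus generator

`generate_fundus()` draws a reddish disc with radial falloff on a black
frame, an offset optic-disc highlight, dark random-walk vessel curves,
and two grade-correlated lesion families inside the disc: dark dots
(microaneurysm/haemorrhage stand-ins) with Poisson counts at rates
(0, 5, 12, 22, 35) for grades 0-4, and bright yellowish blobs (exudate
stand-ins) at rates (0, 2, 5, 9, 14). Gaussian pixel noise (sigma 3) is
added inside the disc. Every image is deterministic given its seed and
grade, and ground truth (centre, radius, planted counts) is attached as
attributes.

Three geometric choices are deliberate. The default canvas is 128 px so
the preprocessing windows (7/21-px non-local means, 10-px opening) are
meaningful before the model-side downscale to 16 x 16. Dark dots are
3-4.5 px so they survive that downscale as local darkening. Bright blobs
are 6-8.5 px — *larger than the 10 x 10 opening kernel* — because opening
erases smaller bright structures; smaller exudates would be silently
removed by the pipeline's own noise stage and the class signal would
vanish. The rates were chosen once so that adjacent grades remain
separable through the full chain; they are declared here and not
revisited.

What passing tests on this generator shows: that every stage operates
correctly on images with the right gross structure, that the class
signal survives preprocessing, and that the full model can fit such a
signal quickly at 16 x 16. What it does not show: performance on real
fundus photographs, whose lesions, vessel trees, illumination fields and
inter-grader label noise are far richer than this stylized model. No
accuracy measured here transfers to clinical data.

## Desk-scale problem sizes

The test suite exercises training at deliberately small sizes chosen as
the package's own desk-scale study conditions: the learning sanity check
uses 500 synthetic images (100 per grade), preprocessed and downscaled to
16 x 16, trained for 30 epochs with batch size 64 at three seeds, and the
reduction protocol runs at fractions 1.0 and 0.5 with two repeats and
short schedules. Unit tests use smaller fixtures still (tiny
configurations with an 8-wide embedding for gradient checks).

## Known limitations

- JPEG reading is not supported (PNG and TIFF are); the batch tools and
  fixtures use PNG.
- Micro versus macro averaging for the ten evaluation metrics is exposed
  as a flag (`metric_report(average=)`) because published single-scalar
  tables do not state the convention; macro is the default.
- The attention implementation loops over samples within a batch; it is
  sized for the low-resolution regime the method targets (tens of
  tokens), not for large images.
- `undersample()` reduces exactly the two largest classes to the cap,
  matching the published balancing algorithm, rather than capping every
  class above the threshold.
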