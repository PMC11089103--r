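---
title: "Methods: hierarchical transformer segmentation of skin histopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical transformer segmentation of skin histopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitseg)
```

## Scope and assumptions

`mitseg` segments H&E histopathology images of non-melanoma skin cancer
into twelve classes: the carcinomas BCC, SCC and IEC, the tissue classes
GLD, FOL, INF, RET, HYP, PAP, EPI, KER, and background (BKG). The design
assumes flat RGB rasters (TIFF) with paired colour-coded masks (PNG) at a
native pitch of 0.67 µm/pixel, optionally pre-reduced 2×/5×/10×; it does
not read pyramidal whole-slide formats. The model is a hierarchical Mix
Transformer (MiT) encoder feeding an all-MLP decoder; everything —
including backpropagation and Adam — is explicit R matrix code, so each
computational step can be inspected and unit-tested in isolation.

## Encoder

Each of the four stages applies overlapped patch merging, a stack of
transformer blocks, and a closing layer normalisation.

**Patch merging.** A K×K strided convolution with stride S and zero
padding P, followed by layer normalisation. Stage 1 uses K=7, S=4, P=3;
stages 2–4 use K=3, S=2, P=1. The stage-1 stride is pinned by the output
contract — the first pyramid level must sit at 1/4 of input resolution
(`floor((512 + 6 − 7)/4) + 1 = 128`), and the four strides must multiply
to 32 so the last level sits at 1/32. A stride of 3 with K=7, which
sometimes appears in descriptions of this architecture family, is
incompatible with both constraints and is treated here as a transcription
slip. The 4×-downsampling interpretation of "4×4 patches" is realised by
the overlapped merge itself, not by a non-overlapping cut.

**Spatial-reduction attention.** Standard multi-head attention
`softmax(QKᵀ/√d_head)V` with head dimension `d_head = C_i / N_i`, except
that keys and values are first passed through a spatial reduction: the
H×W token grid is regrouped into non-overlapping R×R blocks (a strided
projection with kernel = stride = R), mapped from R²·C features back to C,
and layer-normalised. Sequence length therefore drops by R² before the
score matrix is formed. We use per-dimension ratios R = (8, 4, 2, 1),
i.e. sequence-length reductions (64, 16, 4, 1); reading the reduction
factors as per-dimension values of 64/16/4 instead would attach
multi-million-parameter reduction projections to stage 1 and is
inconsistent with the published family sizes (next section). R must tile
the token grid exactly; non-tiling inputs are an error rather than a
silent crop.

**Mix-FFN.** `Linear(C → 4C) → depthwise 3×3 convolution → GELU →
Linear(4C → C)`, added residually. The zero-padded depthwise convolution
injects position, so the encoder carries no positional encoding and
accepts any admissible input size without interpolating anything.
Pre-norm residual wiring is used in both halves of the block.

## Registry and parameter accounting

Four variants are registered. All share heads (1, 2, 5, 8), ratios
(8, 4, 2, 1) and expansion 4; they differ in stage depths and widths:

| variant | depths | widths | encoder parameters |
|---|---|---|---|
| mit-b0 | 2,2,2,2 | 32,64,160,256 | 3,319,392 |
| mit-b2 | 3,4,6,3 | 64,128,320,512 | 24,196,288 |
| mit-b3 | 3,4,18,3 | 64,128,320,512 | 44,072,128 |
| mit-b5 | 3,6,40,3 | 64,128,320,512 | 81,443,008 |

`count_parameters()` and `init_params()` consume the same shape manifest,
so the count is by construction the size of the network that training
updates; a test materialises the weights and checks the identity. These
totals pin several architectural choices jointly: biases on the Q/K/V and
output projections, a depthwise (not dense) Mix-FFN convolution,
expansion factor 4, the strided-projection form of the spatial reduction,
and a per-stage closing layer normalisation. The totals are encoder-only;
the decoder width is a free choice (default 256, conventional for this
decoder family) and is accounted separately under `scope = "decoder"`.
The B0 total is occasionally printed elsewhere as 3,319,292; the
arithmetic of the family geometry gives 3,319,392, and the same geometry
reproduces the B2/B3/B5 totals digit for digit, so we report the computed
value rather than adjusting any structure toward a 100-parameter
difference.

## Decoder

Each pyramid level is linearly mapped to the unified width, bilinearly
upsampled to the 1/4-resolution grid (half-pixel centres, corner
alignment disabled — documented for bit-reproducibility), concatenated to
4C channels, fused to C, passed through GELU (the decoder's hidden
activation) with dropout, and projected to one logit per class. The
upsampling target is the H/4 × W/4 grid of the first level. Full-size
masks come from bilinearly upsampling the logits to image resolution and
taking the per-pixel argmax (ties broken toward the lower class index,
which is measure-zero for continuous logits).

## Data pipeline

* **Mask codec.** Masks are colour-coded PNGs; the codec is a strict
  bijection between the 12 palette colours and codes 0..11, and any
  off-palette pixel aborts with the offending colours and counts. The
  palette itself is a configurable asset (the reference palette is only
  published as a figure); the default is 12 maximally distinct colours
  with a white background.
* **Resolution variants.** Images are reduced by block averaging (area
  interpolation); masks always by nearest neighbour — label arithmetic
  must never interpolate. Pixel pitch scales as 0.67·factor µm.
* **Tiling.** Non-overlapping 256×256 tiles, right/bottom tiles padded
  with white pixels and BKG labels; padded pixels are recorded in a
  validity mask and excluded from loss and metrics. Tiles are rescaled to
  512×512 (image bilinear, labels nearest) for the model and stitched
  back by inverse rescaling and placement; the round trip is exact on the
  unpadded area. Coordinates are 0-based, row-major, half-open.
* **Splitting.** 80/10/10, stratified over cancer-type × biopsy-type
  cells with largest-remainder rounding and a seeded shuffle inside each
  cell, so both cancers and biopsy kinds spread evenly. Augmentation is
  applied only to training tiles after splitting, avoiding leakage of
  rotated copies across splits; the alternative ordering (augment before
  split) is not used anywhere in the package.
* **Augmentation.** The 8 dihedral symmetries of the square, applied
  identically to image and mask, original first, deterministic order.
  Class pixel counts are invariant — a property the tests assert.

## Synthetic fixtures

The generator emulates the statistical skeleton of the real dataset so
that every module is testable without any download: a background-dominant
canvas (BKG target 58.6%, the published pixel share) containing one
wobbly elliptical tissue blob whose nested bands follow anatomical order
(keratin and epidermis at the rim, papillary then reticular dermis,
hypodermis deepest), carcinoma blobs seeded in the dermis, and small
gland/follicle/inflammation islands. Class frequencies default to the
published distribution; thin rims are widened to a ≥2-pixel minimum so
every requested class survives pixelisation on small canvases. Textures
are flat per-class colours plus spatially correlated Gaussian noise
(σ = 0.06 before blurring, blur σ = 1.5 px) — deliberately not a stain
simulation. Cancer and biopsy metadata follow the real slide mixes
(140:60:90 BCC:SCC:IEC; 100:58:132 shave:punch:excision).

Passing tests on these fixtures demonstrates that the code paths are
correct and that the architecture can extract learnable signal; it says
nothing about accuracy on real H&E tissue, where texture, staining
variability and boundary ambiguity dominate.

## Training and calibration

Defaults: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at learning rate 6e-4,
batch size 8, 50 epochs, dropout 0.1 (after the attention projection,
inside Mix-FFN, and on the decoder hidden layer), layer-norm ε = 1e-6,
no schedule, no weight decay, plain unweighted cross-entropy. The loss is
computed at full mask resolution on bilinearly upsampled logits — masks
are never downsampled to the logit grid, because nearest-neighbour label
reduction would discard thin structures; invalid (padded) pixels are
excluded. Weight initialisation is Glorot-normal with zero biases and
unit layer-norm gains. Training is deterministic given the config seed
(initialisation, shuffling and dropout all draw from it); bitwise
reproducibility assumes a single-threaded BLAS.

Temperature scaling fits a single scalar T minimising validation NLL of
`softmax(logits/T)` by a 1-D search over log T ∈ [log 0.05, log 50]
(`stats::optimize`, tolerance 1e-6); if the search cannot improve on
T = 1, T = 1 is kept, and single-class validation data degenerates to
T = 1 with a warning. Calibration is fitted on validation pixels only.
Because division by a positive scalar preserves logit order, calibrated
and uncalibrated argmax masks are identical — accuracy and mIoU are
invariant, which the tests assert. Uncertainty is `1 − max_c p_c`, in
[0, 11/12] for twelve classes.

## Evaluation

All metrics derive from a K×K pixel-count confusion matrix (rows =
truth), which is additive over image partitions and therefore streamable
over tiles. Class-wise accuracy is recall `cm[k,k]/rowsum_k`; classes
absent from the ground truth are reported as missing, not zero, and are
excluded from macro means — the convention that makes the macro mean of a
published per-class table reproduce its published average exactly.
"Average accuracy" is the macro mean of recalls; mIoU averages
`cm[k,k]/(row_k + col_k − cm[k,k])` over present classes; F1 is reported
in micro (= overall pixel accuracy), macro and support-weighted variants,
since which averaging a given published F1 uses is generally unstated.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; the SRA-vs-full-attention
  equivalence at R = 1 is asserted against a brute-force per-row oracle
  at tolerance 1e-5 on grids up to 16×16.
* Patch merging rejects inputs whose output dimension would fall below 1;
  `encode()` requires at least 32×32 images.
* Bilinear resizing clamps source coordinates at the borders (half-pixel
  convention); nearest-neighbour resizing uses floor-of-centre indexing.
* Tie-breaks: argmax takes the first maximal class; largest-remainder
  apportionment breaks ties by the larger fractional part in list order.
* Composed downsampling (e.g. 2× twice) is permitted; the specimen's
  resolution factor multiplies.

## Problem sizes in the test suite

The suite exercises the real registry (including one full MiT-B0 encode
at 512×512 and one at 64×64 to pin the pyramid geometry) but trains only
a reduced variant — widths (8, 16, 24, 32), depth 1 per stage, heads
(1, 2, 4, 8), decoder width 32 — for 200 gradient steps on eight 64×64
synthetic specimens. Those sizes were chosen as the smallest
configuration that demonstrably beats the majority-class baseline mIoU
with margin; the default heads (1, 2, 5, 8) do not divide the reduced
widths, so the reduced variant overrides them (the validator enforces
divisibility rather than silently adjusting).

## Known limitations

* Pure-R execution is orders of magnitude slower than GPU frameworks;
  the package targets inspectability and desk-scale experiments, not
  slide-throughput inference.
* No ImageNet pre-training loop is provided; externally pre-trained MiT
  weights can be mapped into the flat checkpoint container by key
  renaming, but no downloader is included.
* Class imbalance is left to plain cross-entropy (no class weights or
  focal losses), matching the reference training setup.
* The fixture generator does not model nuclei, stain physics or scanner
  artefacts; conclusions about real-data accuracy require real data.
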