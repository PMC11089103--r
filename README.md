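# mitseg

Twelve-class semantic segmentation of non-melanoma skin-cancer
histopathology with a hierarchical Mix-Transformer (MiT) encoder and a
lightweight all-MLP decoder, implemented end to end in R.

## The problem

Haematoxylin-and-eosin slides of basal cell carcinoma (BCC), squamous cell
carcinoma (SCC) and intraepidermal carcinoma (IEC) are read by pathologists
tissue by tissue: keratin and epidermis at the surface, papillary and
reticular dermis beneath, hypodermis at depth, with glands, follicles and
inflammation scattered through the dermis. A segmentation model that labels
every pixel with one of these twelve classes (the three carcinomas, eight
tissue types, and background) mirrors how pathologists reason and provides
an interpretable substrate for downstream cancer detection, classification
and surgical-margin assessment.

`mitseg` is aimed at computational-pathology researchers who want a fully
inspectable reference implementation of this pipeline — architecture,
training, calibration, and evaluation — with no deep-learning framework
dependency: every layer's forward and backward pass is explicit R matrix
code.

## The model

The encoder is a four-stage hierarchical Mix Transformer. Stage *i*
produces features at 1/4, 1/8, 1/16, 1/32 of input resolution with channel
widths C₁..C₄:

* **Overlapped patch merging** — a strided K×K projection (stage 1:
  K=7, S=4, P=3; stages 2–4: K=3, S=2, P=1) followed by layer
  normalisation; overlap (K > S) preserves local continuity between
  patches.
* **Spatial-reduction attention (SRA)** — multi-head self-attention
  `softmax(QKᵀ/√d)V` in which the key/value sequence is first shortened by
  R²: the token grid is regrouped into R×R blocks of R²·C features,
  projected back to C and layer-normalised. With per-stage R = (8,4,2,1)
  the sequence-length reductions are (64,16,4,1), cutting the O(N²)
  attention cost to O(N²/R²).
* **Mix-FFN** — `MLP → depthwise 3×3 conv → GELU → MLP` with hidden width
  4C; the zero-padded convolution leaks position, so no positional
  encoding is needed at any resolution.

The all-MLP decoder linearly maps each pyramid level to a unified width,
bilinearly upsamples everything to the 1/4-resolution grid, concatenates,
fuses, and projects to one logit per class; logits are bilinearly
upsampled to image resolution and arg-maxed into a mask. Prediction
confidence is calibrated by temperature scaling (a 1-D NLL minimisation on
validation pixels) and visualised as per-pixel uncertainty
`u = 1 − max_c p_c`.

Four encoder variants are registered (`mit-b0/b2/b3/b5`), differing in
per-stage depths and widths. `count_parameters()` enumerates every
trainable array of the instantiated network.

## Worked example

Inspect an architecture and its exact size:

```
> mitseg_cli(c("params", "mit-b0"))
Mix-Transformer spec: mit-b0
  depths          2,2,2,2
  attention heads 1,2,5,8
  hidden dims     32,64,160,256
  sr ratios       8,4,2,1
  merge K/S/P     7,3,3,3 / 4,2,2,2 / 3,1,1,1
  mlp ratio 4  decoder dim 256  classes 12
encoder  3,319,392 parameters
decoder  397,580 parameters
full     3,716,972 parameters
```

The encoder count is the sum over every projection, attention, Mix-FFN and
normalisation array of the four stages; the decoder adds the four
unifying linears, the fusion layer and the classifier at width 256.

Train a deliberately tiny variant on synthetic fixtures (64×64
pseudo-specimens whose class frequencies follow the real dataset's
background-dominant profile) and compare against the majority-class
baseline:

```r
library(mitseg)
tiny <- resolve_spec("mit-b0", list(
  hidden_dims = c(8L, 16L, 24L, 32L), depths = c(1L, 1L, 1L, 1L),
  attention_heads = c(1L, 2L, 4L, 8L), decoder_dim = 32L))
specimens <- generate_dataset(8, seed = 11, size = 64)
model <- train(seg_model(tiny, seed = 11), specimens, list(),
               train_config(batch_size = 1L, epochs = 25L, seed = 11))
tail(model$history$train_loss, 1)
#> [1] 0.7479038
```

Over the 200 gradient steps the cross-entropy falls from ~2.5 (the ln 12
of uniform guessing) to 0.748, and the trained model reaches a training
mIoU of 0.193 versus 0.049 for always predicting the most frequent class —
the fixtures carry learnable signal and the hand-derived backpropagation
optimises it.

The full pipeline is also scriptable from the shell: `fixtures`, `tile`,
`train`, `predict`, `evaluate` (confusion matrix, class-wise accuracy,
mean IoU, micro/macro/weighted F1) and `uncertainty` (calibration
temperature plus grey-scale and overlay uncertainty maps).

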