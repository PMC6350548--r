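---
title: "Methods: dense encoder-decoder segmentation of mammographic masses"
author: "mammoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense encoder-decoder segmentation of mammographic masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-image breast-tumor segmentation in digital mammograms is hard for
three reasons this package is organized around. First, masses vary widely
in size: at full clinical resolution (4096-pixel image height) their
bounding boxes span roughly 200 to 800 pixels, so any fixed receptive
field misses either the small or the large end. Second, after resizing a
mammogram to a tractable network input (512 x 512), a 200-pixel mass
shrinks to roughly 30 pixels, and an encoder that downsamples 32-fold can
erase it entirely. Third, tumor pixels are a tiny fraction of the image,
so an unweighted pixel loss is dominated by background and the classifier
collapses toward "everything is background".

# The model

The segmentation network is a fully convolutional dense network
(FC-DenseNet) with an atrous-spatial-pyramid-pooling (ASPP) bottleneck.

**Dense blocks.** Each dense layer is batch normalization, ReLU, a 3 x 3
same convolution producing `growthRate` feature maps, then dropout
(p = 0.2). Layer *i* receives the concatenation of the block input with
the outputs of layers 1..*i*-1, so its input width is
`inChannels + (i-1) * growthRate`. The block's output is the
concatenation of the layer outputs only (`layersPerBlock * growthRate`
maps); the block input is *not* folded into the output, which keeps
channel counts from growing linearly along the decoder.

**Transitions.** A transition down is BN, ReLU, a 1 x 1 convolution that
conserves the number of feature maps, dropout, and then a 3 x 3 stride-2
convolution. The stride-2 convolution replaces the 2 x 2 max pooling of
the original design so that downsampling is learned rather than lossy. A
transition up is a single 3 x 3 stride-2 transposed convolution, applied
only to the preceding dense block's output. On the downsampling path the
concatenation of each dense block's input and output is stored as a skip
tensor and concatenated back in at the same resolution on the way up.

**Why four transitions and an ASPP bottleneck.** The baseline
FC-DenseNet56 (growth 12, 4 layers per block, 5 transitions) downsamples
by 32; a 30-pixel mass is below one bottleneck pixel. The proposed
variant removes one transition (downsample factor 16) and replaces the
bottleneck dense block with ASPP: four parallel branches over the same
input -- a 1 x 1 convolution and three 3 x 3 atrous convolutions with
sampling rates 6, 12 and 18 -- each producing `asppBranchChannels` maps,
concatenated together with the block input and fused by a final 1 x 1
convolution. An atrous convolution at rate *r* spaces its taps *r* pixels
apart, enlarging a k x k kernel's support to k + (k-1)(r-1) without
adding parameters, so the pyramid sees fields of view of 3, 13, 25 and 37
pixels at the 32 x 32 bottleneck and fuses them.

**Layer accounting.** Counting the initial convolution, every dense-layer
convolution, one layer per transition, the five ASPP convolutions (or the
four bottleneck dense layers in the baseline) and the classifier
convolution gives 1 + 16 + 4 + 5 + 4 + 16 + 1 = 47 layers for the
proposed network and 1 + 20 + 5 + 4 + 5 + 20 + 1 = 56 for the baseline.
This is the accounting convention under which both published totals hold
simultaneously; it treats a transition as one counted unit even though
the transition down also contains the channel-conserving 1 x 1
convolution as a learnable layer. `countLayers()` implements exactly this
convention.

**The loss.** With per-class pixel frequencies $f_l$ (summing to 1 over
background and tumor), the training loss is the inverse-frequency
weighted cross-entropy

$$L = -\frac{1}{N}\sum_{i=1}^{N} \frac{1}{f_{y_i}} \log p_i,$$

where $N$ is the pixel count, $y_i$ the true label of pixel $i$ and
$p_i$ the predicted probability of that label. At a typical foreground
fraction of 1%, a tumor pixel's gradient is ~99 times a background
pixel's, which is what keeps foreground recall alive under extreme
imbalance. Plain cross-entropy and soft Dice loss
($1 - (2\sum p_i g_i + s)/(\sum p_i + \sum g_i + s)$, smoothing $s = 1$)
are provided as ablation comparators.

**Metrics.** From pixel confusion counts, the package reports the Dice
index $DI = 2TP/(2TP+FP+FN)$, pixel accuracy $PA = TP/(TP+FN)$ (note:
this is foreground recall, not global accuracy) and
$IOU = TP/(TP+FN+FP)$. The identity $DI = 2\,IOU/(1+IOU)$ is enforced by
property tests. Set-level summaries are unweighted per-image means
("mean Dice index"); pooled-count aggregation is available behind a flag.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `growthRate` | 12 | feature maps added per dense layer |
| `layersPerBlock` | 4 | dense layers per block |
| `nTransitions` | 4 (proposed) / 5 (baseline) | downsampling steps per path |
| `asppRates` | 6, 12, 18 | atrous sampling rates of the pyramid |
| `initialFeatures` | 48 | channels after the first convolution |
| `asppBranchChannels` | 48 | maps per ASPP branch |
| `dropoutRate` | 0.2 | dropout after every dense-layer convolution |
| `inputSide` | 512 | network input side (px) |
| learning rate | 0.001 | Adam, default betas (0.9, 0.999) |
| batch size | 1 | protocol value; batch norm therefore normalizes per image |
| epochs | 100 | full protocol; desk-scale runs cap steps instead |

Two widths are genuinely open design choices (the published description
fixes neither): `initialFeatures = 48` follows the original FC-DenseNet
convention, and `asppBranchChannels = layersPerBlock * growthRate = 48`
keeps the pyramid's channel flux comparable to the dense bottleneck it
replaces. Both are configurable. Dropout is not applied inside the ASPP
branches.

# Preprocessing

Images are resized to the network side with bilinear interpolation
(masks with nearest-neighbor so they stay binary), intensities rescaled
into [0, 1] and the mean subtracted. Both open readings of the
normalization are implemented: per-image min-max (default; robust across
DICOM bit depths and self-contained at inference) and fixed-range
division by a stated maximum; likewise per-image versus supplied
(dataset) mean. Constant images map to zeros rather than dividing by
zero. Class frequencies for the weighted loss are computed per image at
loss time by default -- the imbalance the weighting corrects varies image
by image -- with a dataset-wide mode available by passing precomputed
frequencies.

# The tensor backend

No R deep-learning framework is assumed: the package ships a compact CPU
backend. Convolution is im2col plus a BLAS matrix multiply; the
transposed convolution is implemented as the exact adjoint of the paired
stride-2 convolution, which both guarantees exact spatial doubling and
makes its gradient the forward convolution. A small reverse-mode tape
records per-op closures so dense connectivity, skip concatenations and
the ASPP fan-out all receive correct gradients; every kernel is verified
against central differences (~1e-10 relative error) and against a naive
O(n^4) loop oracle in the test suite. Batch size is fixed at 1
(the protocol's value), which keeps the backend simple and makes batch
normalization per-image by construction.

Numerical choices: predicted probabilities are clamped to [1e-7, 1]
before logs; class frequencies are floored at 1e-4 (so tumor-free images
keep a finite loss) and renormalized; batch-norm epsilon is 1e-5 with
running-statistic momentum 0.1; "same" convolutions zero-pad by
(effective kernel - 1)/2; weight init is He-uniform scaled by fan-in with
identity-initialized batch norm, all under a caller-supplied seed. An
odd spatial side arriving at a stride-2 transition is an error (strict
mode): inputs must be divisible by the downsample factor. When an ASPP
rate's effective kernel exceeds the bottleneck side (as rate 18 does at
a 512 input: 37 > 32) the assembler warns but proceeds -- zero padding
makes the operation well defined, and this is the published
configuration.

# Inference and training conventions

Inference binarizes by argmax (equivalently, tumor probability >= 0.5)
at the network side, then nearest-neighbor resizes the mask back to the
source resolution. Training uses no learning-rate schedule, weight
decay, early stopping or augmentation -- none is part of the protocol --
and when validation data are given the checkpoint with the best
validation mean Dice index is kept (the protocol does not state which
checkpoint is evaluated; best-validation is this package's choice, with
the full history serialized so last-epoch evaluation remains possible).

# The phantom generator

Clinical mammogram datasets are private, so the package renders paired
synthetic phantoms with exact ground truth: a dark background, a bright
half-elliptical breast region anchored at the chest-wall edge with 2-3
octaves of smoothed-noise texture, an optional brighter pectoral wedge
(MLO-like views), and tumors rendered as rotated ellipses with a radial
sinusoidal boundary perturbation (amplitude at most 20% of the radius, 3-7
lobes) at intensity local-tissue-plus-contrast. Tumor bounding boxes are
drawn from the 200-800 pixel clinical interval scaled proportionally to
the canvas; rendered boxes are measured and enforced against that range.
Default contrast 0.3 against noise sd 0.02 is the easy regime; setting
contrast near the noise sd gives the hard low-contrast regime.

What the phantoms do and do not establish: they reproduce the geometry,
the intensity ordering (background < tissue < tumor), the size
distribution and the ~1-3% foreground fraction that motivates the
weighted loss, so passing tests demonstrate that the architecture,
gradients, loss weighting and evaluation chain work end to end. They do
not reproduce real parenchymal texture, overlapping glandular structure,
calcifications or acquisition artifacts, so phantom scores say nothing
about clinical accuracy; published test-set numbers are not reproducible
without the clinical data, and the package does not attempt them.

# Desk-scale problem sizes

The demonstration and test configuration is `tinyArchConfig()`: growth 4,
2 layers per block, 2 transitions, ASPP rates 2 and 4, 16 initial
features, 64 x 64 inputs (~32k parameters). Four phantoms, 300 Adam
steps of weighted cross-entropy, drive the training loss below 0.05 and
the training-set mean Dice index above 0.8 in about two minutes on one
CPU -- the package's memorization sanity check, which fails if any branch
(including every ASPP rate) stops passing gradient. The ablation check
trains weighted versus plain cross-entropy for 200 matched steps on
low-contrast phantoms (contrast 0.06) and verifies the weighted run's
foreground recall is at least the unweighted run's, and that both beat
the double-threshold baseline -- direction, not magnitude, is the claim
at this scale.

# Classical baseline

The double-threshold baseline first finds a global threshold with the
ISODATA (Ridler-Calvard) iteration -- the canonical reading of
"iterative threshold segmentation": t is replaced by the midpoint of the
means below and at-or-above t until it moves less than 1e-3 -- then uses
the mean intensity of the first-pass region as a second threshold
applied to the whole image. Postprocessing deletes 8-connected
components smaller than 0.1% of the image (no published cutoff exists;
that default is this package's choice, as is 8-connectivity). Whether
the second threshold applies within the first region only or to the
whole image is ambiguous in prose; whole-image is implemented, which
makes the final mask the brightest-structure selection and is monotone:
raising the second threshold never adds pixels.

# Degenerate inputs and conventions

* Both masks empty: DI, PA and IOU are defined as 1 with a warning
  (correct rejection of a tumor-free image should not score 0); every
  clinical evaluation image contains a tumor, so the convention never
  touches comparable numbers.
* Tumor-free training images: the frequency floor keeps the weighted
  loss finite.
* Constant images: preprocessing returns zeros; the iterative threshold
  refuses them explicitly.
* Splits: the 230/75/75 image-level split is reproduced exactly and
  deterministically from a seed. 230 is odd, so that split cannot be
  patient-paired; a patient-aware mode (both views of a patient stay in
  one partition) is provided and recommended when patient identity is
  known.

# Known limitations

The backend is CPU-only and single-image; training the full 512 x 512,
47-layer configuration for 100 epochs is out of desk scale, and the
package makes no claim to reproduce clinical test metrics. DICOM support
covers uncompressed little-endian single-frame grayscale files only.
Phantom realism is deliberately limited to the features the method's
assumptions rest on.
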