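---
title: "hemaseg: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemaseg: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A stained peripheral blood smear viewed under a light microscope is a dense
carpet of erythrocytes (RBCs) with occasional leukocytes (WBCs) and
platelets. Semantic segmentation assigns one of four labels to every pixel
— background 0, RBC 1, WBC 2, platelet 3 — which in turn supports
pixel-level counting of the three cell classes, a quantity proportional to
the cellular composition a hematologist reads off a differential count.

`hemaseg` implements the full workflow: synthetic data generation with
exact ground truth, mask preprocessing, a convolutional encoder-decoder
segmenter, minibatch SGD training, a three-family evaluation suite
(accuracy, IoU, boundary-F) and classwise pixel counting, driven by one
YAML-configured CLI.

## The synthetic smear world

Real mask-annotated whole-slide smear collections are small, external and
license-bound, so every stage here is testable against a parametric
generator instead. A scene is a list of elliptical cell records on a canvas
(default 512×512; full-scale slides of 2592×1944 are emulated at desk scale
and all sizes are configurable):

* **RBC**: semi-axes ~N(9, 1)×N(7.5, 1) px, pinkish-red, with a lighter
  central pallor disc (the biconcave look) on 90% of cells.
* **WBC**: semi-axes ~N(16, 2)×N(14, 2) px, purple cytoplasm with a darker
  nuclear sub-ellipse covering 55–80% of the radius.
* **PLT**: semi-axes ~N(3.5, 0.5)×N(3, 0.5) px, small purple fragments.

A pixel belongs to a cell iff its center satisfies the ellipse inequality
(0-based pixel `(r, c)` has center `(r+0.5, c+0.5)`); this rule is
deliberately trivial so a brute-force pointwise rasterizer can serve as an
independent oracle in the tests. Same-class overlaps union in the binary
masks; cross-class overlaps are resolved by label priority (platelet over
WBC over RBC) when masks are fused. Additive Gaussian color jitter
(sd 0.02 on the [0,1] intensity scale) is applied to the image only, never
to masks.

**Frequency-driven cell counts.** The default class pixel frequencies are
93.55 / 6.09 / 0.34 % (RBC / WBC / PLT) of the foreground, the composition
typical of a smear field. Rather than hand-picking cell counts, the
generator inverts these targets: with canvas area $A$, target foreground
coverage $\phi$ (default 0.55) and mean cell area $a_c$, the pixels wanted
per class are $P_c = f_c\,\phi A$, corrected for the area that
higher-priority classes will overwrite, and the count follows from the
Poisson coverage model $\mathrm{union}(n) = A(1 - e^{-n a_c / A})$. On the
default canvas this yields ≈ 940 RBCs, 13 WBCs and 15 platelets per slide,
and measured fused frequencies land within a fraction of a percentage
point of the targets. Edge clipping (centers are uniform over the canvas)
costs all classes a similar few percent of area and cancels in the ratios.

What the generator does **not** emulate: stain physics and illumination
gradients, cell-type morphology beyond ellipses (no biconcave geometry, no
lobed nuclei), leukemic blasts, focus blur, and spatial clustering of
platelets. A green test therefore establishes that the pipeline machinery
is correct and can learn separable stain/size cues — not that the network
generalizes to real slides.

A second stated world is used in the desk-scale training tests: a 64×64
field crop with 12 RBCs, one WBC and two platelets, matching the default
areal density of the 512×512 world.

## Preprocessing

Mask images are reduced to one channel by Rec.601 luminance when RGB, then
thresholded. Foreground is `value > 0` by default; a `dark_on_light`
polarity accepts the black-cells-on-white-sheet convention some annotation
tools produce. Label fusing starts from a zero grid and assigns IDs in
order RBC=1, WBC=2, PLT=3, later writes overwriting earlier ones. Labels
are resized with nearest-neighbor only — interpolation must never invent
fractional class IDs — while images use bilinear. The train/test split is
uniform without replacement and seed-deterministic (the reference regime is
103 train / 5 test of 108 slides; the package defaults reserve ~5% for
testing at any dataset size).

## The encoder-decoder network

The segmenter is a VGG-style encoder — stages of 3×3 conv + ReLU blocks
followed by 2×2 max pooling, channel widths `c(64,128,256,512,512)` at
full scale — mirrored by a decoder that upsamples back to full resolution
and ends in a per-pixel softmax over 4 classes. All forward/backward passes
are implemented in RcppArmadillo; no GPU or deep-learning framework is
required, which bounds the practical scale (desk-scale specs such as widths
`c(8,16)` or `c(16,32)` train in seconds to minutes on one CPU).

Design choices where the design was genuinely open:

* **n_classes = 4.** The three cell classes plus background: the
  complement/unity mask implies background pixels exist and must be
  predicted; evaluation then reports the three foreground classes.
* **Decoder upsampling: max-unpooling by default.** The mirrored decoder
  was first built with nearest-neighbor upsampling + conv. On the one-image
  capacity test that variant plateaued near 97% pixel accuracy: without any
  path carrying pixel-accurate positions past the pooling stages, a
  translation-invariant decoder cannot localize boundaries, and boundary
  pixels are ~15–20% of a dense smear crop. Reusing the encoder's pool
  argmax indices (SegNet-style max-unpooling) restores that information,
  reaches >99% on the same budget, and is the established construction for
  VGG encoder-decoders without skip connections. `"nearest"` remains
  available in `network_spec(decoder_upsampling=)`.
* **Input padding, not rejection.** The conventional 300×300 input is not
  divisible by `2^depth` for a 5-stage encoder; images are padded
  internally by edge replication to the next valid size and score maps
  cropped back, keeping 300×300 as a user-facing default rather than
  erroring.
* **Pretrained encoder as a hook only.** `load_encoder_weights()` can
  inject an externally obtained VGG-style encoder; nothing is downloaded,
  and random He initialization is the default.

## Training

Minibatch SGD with momentum 0.9 (the framework-family convention; the
reference regime names only batch size 1, 500 epochs, initial learning
rate 1e-3) minimizes per-pixel softmax cross-entropy at a constant
learning rate, reshuffling each epoch with the config seed. An epoch is
`ceiling(n_train / batch_size)` iterations; each iteration logs minibatch
pixel accuracy (background included) and loss. Optional median-frequency
class weighting counteracts the ~93.5/6.1/0.3 imbalance under which
platelets contribute almost no gradient; it is off by default to mirror
the reference regime's silence. Checkpoint selection defaults to the
final-epoch model (the reference account reports both a best-accuracy and
a best-loss epoch without stating which was tested); periodic checkpoints
plus `--checkpoint` let a user choose otherwise.

Learning-rate caveat: at desk scale the loss surface is stiff — constant
lr 0.01 with momentum 0.9 fits one slide to >99% in 200 steps on the
`c(16,32)` spec, while 2× that rate can collapse to the majority class.
The tests pin known-good small-scale settings (0.005–0.01).

## Evaluation

All metrics derive from a 4×4 pixel confusion matrix accumulated over the
test split; summaries restrict to the three foreground classes unless
`include_background = TRUE`.

* **Per-class accuracy** defaults to recall `TP/(TP+FN)`. The textbook
  form `(TP+TN)/(TP+TN+FP+FN)` is provided as mode `"eq1"` but is not the
  default: under a 0.34% platelet prevalence it returns ≈1 on true
  negatives alone, which is inconsistent with sub-0.9 platelet accuracies
  reported alongside it in the source material's own tables.
* **Global accuracy** is trace over total for the evaluated classes, and
  satisfies `GlobalAccuracy = Σ_c freq_c · recall_c` exactly.
* **IoU** is `TP/(TP+FP+FN)`; `MeanIoU` the unweighted class mean,
  `WeightedIoU` the true-pixel-frequency weighted mean.
* **Boundary-F (BF)** extracts boundary pixels (foreground pixels
  4-adjacent to background or the image edge), matches them within a
  Euclidean tolerance defaulting to 0.75% of the image diagonal (the
  established convention), and returns `2PR/(P+R)`; both empty boundaries
  give 1 (identical masks), one empty gives 0. `MeanBFScore` aggregates by
  mean over test images by default; mean over pooled class scores is the
  alternative — the two differ in general and the package documents which
  it used, since published summary rows are not always the mean of the
  published class rows.

Degenerate inputs: a class absent from both truth and prediction of an
image is skipped in that image's BF aggregation; a class with no true
pixels yields `NaN` accuracy with a warning rather than a silent 1 or 0.

## Counting

`pixel_counts()` tallies label pixels per class (foreground only by
default, matching the three-way frequency split; background joinable by
flag) over one mask or a set, reporting exact integer counts and percent
frequencies. Counts are additive over images and conserve
`foreground + background = canvas` pixels by construction, and both
single-image and image-set scopes are supported because published
per-image frequency figures do not always state their scope.

## Numerical and testing choices

Determinism contracts are exact: scene generation, weight init and
shuffling all run under locally-scoped seeds, so identical (config, seed)
gives byte-identical masks and logs. Softmax is computed with max
subtraction; cross-entropy clamps probabilities at 1e-12. Analytic
gradients are verified against central finite differences in the tests.
Oracle tests (rasterization, confusion/IoU, boundary matching) use
deliberately naive independent reimplementations. Training-dependent tests
are scaled to minutes on one CPU: the bookkeeping identity 500 × 103 =
51500 iterations is asserted arithmetically, while actual training runs
use ≤20 epochs on 16 small slides — full-scale accuracy reproduction is
out of scope by design, as it requires the original external dataset and
GPU-scale training.

## Known limitations

Ellipse-world realism (see above); no stain normalization or illumination
correction (deliberately excluded from preprocessing); O(n·m) boundary
matching, adequate at desk scale; no early stopping or LR schedules; CPU
speed limits full VGG16-width training to demonstration rather than
production use.
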