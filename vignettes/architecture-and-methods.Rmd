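---
title: "Architecture, complexity accounting and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture, complexity accounting and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinyweednet)
```

## The problem and the model

Weed identification on autonomous field equipment has to run on
microcontroller-class hardware: a few hundred kilobytes of RAM, a couple of
megabytes of flash, millijoule energy budgets. Networks intended for that
regime are built exclusively from operators that embedded inference
toolchains execute natively — standard, pointwise and depthwise
convolutions, batch normalization, ReLU/sigmoid, pooling, and dense layers —
and their design is dominated by the parameter/compute budget rather than by
raw capacity.

`tinyweednet` implements one such family. A design point is the triple
*(E, R, S)*:

* **S — stem width.** A 3×3 stride-2 convolution maps the 3×`side`×`side`
  input to S channels at half resolution, with batch norm and ReLU.
* **Multi-scale convolution (MSC) block.** Four stride-1 branches over the
  stem output — 1×1, 3×3, 5×5, and 3×3 max-pool followed by 1×1 — each with
  BN+ReLU, concatenated to 1.5 S channels. The branch widths are equal
  integer quarters of the block width, remainder to the pooling branch.
* **Five inverted residual (IR) blocks** with output widths
  (2, 3, 4, 5, 5) S and strides (2, 2, 2, 2, 1). Each block expands its
  input width C to E·C with a 1×1 convolution (BN, ReLU), filters spatially
  with a depthwise 3×3 (BN, ReLU), re-weights channels with a
  channel-attention (CA) gate, and projects back with a *linear* 1×1
  convolution (BN, **no** activation). A residual shortcut is added only
  when stride is 1 and the widths match — in the default network that is
  exactly the fifth block.
* **R — attention reduction.** The CA gate pools the feature map globally by
  average and by max, pushes both descriptors through a shared two-layer
  bottleneck of hidden width ⌊C/R⌋ (with ReLU between), sums the two
  excitations and applies a sigmoid; the input is then rescaled per channel.
  With every gate parameter at zero the sigmoid yields exactly 0.5, which
  the tests use as a structural probe.
* **Head.** A 1×1 projection to 10 S channels (BN, ReLU), global average
  pooling to a vector, dropout (p = 0.2), and one dense layer to the class
  logits.

For the default point (E = 4, R = 8, S = 24) at 224×224 input, the
activation schedule is 24×112², 36×112², 48×56², 72×28², 96×14², 120×7²,
120×7², 240×7², then a 240-vector and 9 logits; `infer_shapes()` reproduces
it exactly.

The hyperparameter grid is the full factorial E ∈ {3, 4, 6} ×
R ∈ {4, 8, 16} × S ∈ {8, 16, 24} (27 design points), and four ablations
remove one component each: the MSC block (replaced by a single 3×3 branch of
equal width), all CA gates, the depthwise convolutions (replaced by standard
3×3 of identical widths), or the final 1×1 projection.

## Channel schedule for smaller stems

Only the S = 24 schedule is published. Its widths are exact multiples of the
stem width — msc = 1.5 S, IR outputs (2, 3, 4, 5, 5) S, head 10 S — so the
package scales smaller stems proportionally: S = 16 gives
24/(32, 48, 64, 80, 80)/160 and S = 8 gives 12/(16, 24, 32, 40, 40)/80.
Checked against the published complexity table, this rule reproduces the
S = 24 rows to within 0.25% and the S = 8 rows to within about 1%, while the
S = 16 rows come out 1.2–1.6% *heavier* than printed. No rounding convention
in the space we enumerated (make-divisible variants on branch widths,
bottleneck widths, or both) removes that residual, so we keep the
proportional rule and note the S = 16 discrepancy as an unresolvable detail
of the source tables — which are demonstrably noisy elsewhere (see below).

## Parameter accounting and the calibrated conventions

Parameter totals are computed twice and must agree exactly: a closed-form
evaluation on the configuration (`closed_form_parameters()`) and a walk over
the assembled network's tensors (`count_parameters()`). The published totals
pin the bias conventions only indirectly, so we enumerated the plausible
policy space (bias on/off per layer family × attention-bottleneck variants ×
reduced-width rounding) against the printed table and froze the unique
policy that reproduces the default row and the head-less ablation row
simultaneously:

* standard convolutions (stem, MSC branches, expand, project, head 1×1)
  carry biases; depthwise convolutions do not; every BN is affine;
* the CA bottleneck is a shared two-layer MLP with biases on both layers
  *and a batch norm on its hidden layer* (the FC→BN→ReLU gate arrangement
  known from bottleneck-attention modules), hidden width ⌊C/R⌋ by plain
  integer division;
* the classifier carries a bias; model size is 4 bytes per parameter with
  1 MB = 2²⁰ bytes.

Under this policy the default network has **475,803** parameters (printed as
475.8K / 0.4758 M) and **1.815 MB**; removing the final projection gives
**445,203** (printed 445K). Two corollaries came out of the calibration
rather than being imposed: replacing the MSC block by a single 3×3 branch of
equal width leaves the total *unchanged* (7,884 parameters either way, which
matches the published ablation table printing the same 475K for both), and
the MSC branch split must be equal quarters — a divisor-4 make-divisible
split (8, 8, 8, 12) would shift the default total off the printed value.

Two published ablation figures are not reproducible from the stated
architecture: the attention-free variant is printed *larger* than the
baseline (820K vs 475K) even though every closed-form CA term is positive,
and the depthwise-free variant's printed parameter count and model size
disagree with the 4-byte rule. The package asserts the closed-form behavior
(attention removal *decreases* the count; depthwise removal grows it roughly
tenfold, 5.13 M here) and treats those two printed numbers as reporting
noise.

MACC accounting follows the same two-route scheme. The headline figure
counts convolution and dense multiplies only (276.9 M for the default at
224²); deployment toolchains additionally count normalization, activation
and pooling operations with their own proprietary weighting, so the
vendor-reported figure (≈3.1×10⁸) is approximated by the unvalidated
`extended_ops` column and is not an acceptance quantity.

## Training and evaluation protocol

The reference protocol is plain SGD (momentum 0 unless requested), learning
rate 0.001, batch 32, cross-entropy, up to 100 epochs with early stopping
when the monitored accuracy stops improving (patience 10, min-delta 0), and
ten repeats reported as mean ± SD. The monitored metric defaults to held-out
accuracy for fidelity with the protocol; monitoring the test set leaks
information into the stopping time, so a `train_accuracy` monitor is
provided and recommended for hygiene-sensitive use. Macro-averaged F1
(unweighted over classes) is used throughout; metrics are verified against
hand-enumerated confusion-matrix oracles in the tests.

Batch norm uses eps 1e-5 and running-stat momentum 0.1 (biased batch
variance for normalization, unbiased for the running estimate). Weights are
Kaiming-style fan-out normal, BN is initialized to identity, and every draw
is seeded, so assembly and training are bitwise reproducible. Dropout
applies to the pooled vector only, before the classifier, and is inactive at
inference.

## Synthetic data and the desk-scale smoke benchmark

The package never downloads data. `generate_synthetic_dataset()` renders
class-labeled square RGB images with the statistical structure the pipeline
cares about: a soil-toned background with low-frequency clutter and speckle,
elliptical foliage elements whose hue center, texture frequency and size are
class-dependent, and a random global illumination gain. The default
("easy") setting spaces the nine class hues evenly around the color circle
with intra-class hue SD 0.015 and foliage saturation 0.65–0.95 — well away
from the soil background — so class separation is strong by construction.
What the synthetic set deliberately does not model: real leaf morphology,
occlusion, perspective, inter-class similarity of actual weed species, or
natural background diversity. Green tests on it validate the machinery
(gradients, metrics, harness plumbing), not field performance.

The smoke benchmark trains the default architecture at 64-pixel input on
30 images per class (216 train / 54 test after the stratified 8:2 split)
with SGD at learning rate 0.05 and momentum 0.9 for at most 20 epochs — a
setting chosen once as a reasonable plain-SGD recipe for a small,
well-separated problem; the protocol's 0.001 without momentum is tuned for
the full-scale dataset and is far too slow for a 200-step desk run. The run
reaches ≥95% training accuracy in well under 20 epochs on one CPU. The
robustness harness then evaluates the smoke-trained model over the full
6-family × 3-severity corruption grid.

## Corruption suite details

All transforms operate on the normalized [0, 1] float image after resizing,
one at a time, never composed, and never touching labels. Numerical
choices:

* contrast uses a single scalar mean over all pixels and channels;
* blur derives sigma from the kernel side as 0.3·((k−1)/2 − 1) + 0.8
  (0.8, 1.1, 1.4 for k = 3, 5, 7), with reflect-101 borders and a
  normalized separable kernel — a constant image is a fixed point and the
  impulse response is the kernel itself;
* hue severities are listed as ±5°, ±10°, ±15°: each signed shift is
  evaluated separately and the row reports the mean of the two F1 scores,
  the symmetric reading of a single printed row per severity;
* the gamma ladder (0.8, 1.2, 1.6) is kept in its published order even
  though its first level brightens rather than degrades monotonically.

## Exchange format and operator linting

Deployment flows pass through a framework-independent graph exchange. Here
that boundary artifact is a self-describing JSON document (node list with
op types, attributes and named initializers; BN serialized in inference
form; dropout stripped). `run_exported_graph()` is a reference interpreter
that re-executes the file node by node, and the tests require its logits to
match the native forward pass within 1e-4 on every variant.
`check_operator_whitelist()` lints any exchange file against the
embedded-supported operator set; quantization and code generation are
toolchain-internal and out of scope.

## Problem sizes and limitations

Unit tests run on reduced inputs (32–64 px, stem width 8) with full-size
checks confined to the acceptance suite; the acceptance script re-runs the
complete 27-point grid at 224², the smoke training, the robustness grid and
an export round trip. Quantities that inherently require the external
full-scale dataset, long GPU training, or embedded hardware — full-dataset
accuracy, corruption-table scores of the full-scale model, latency, energy,
flash/RAM placement — are declared out of desk scope by
`desk_scale_scope()` rather than approximated.

Known limitations: the S = 16 parameter residual discussed above; training
is CPU-bound R/BLAS and intended for desk-scale verification rather than
full-scale experiments; the exchange format is JSON rather than a protobuf
serialization, chosen so the artifact remains text-only and
self-contained.
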