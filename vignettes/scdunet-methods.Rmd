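---
title: "Segmenting head and neck tumors on T2-weighted MRI: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting head and neck tumors on T2-weighted MRI: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gross tumor volume delineation for head and neck radiotherapy is done on
MRI because of its soft-tissue contrast, but the targets are unforgiving:
a primary tumor (GTVp, at most one per patient) and a variable number of
nodal metastases (GTVn) that together occupy on the order of 0.1 % of the
voxels, with ill-defined borders and heterogeneous intensities. This
package implements a 2D slice-wise segmentation model for that setting,
together with the preprocessing, loss, cross-validation and evaluation
machinery around it, and a synthetic phantom cohort so the entire
pipeline is testable without any clinical data.

## The network

`build_scdunet()` assembles a U-shaped encoder–decoder whose three
distinctive components are exposed as standalone, individually tested
operations.

**Cascaded residual encoder.** Each stage applies two residual blocks in
series, `x' = x + F1(x) + F2(x + F1(x))`, each `F` being two 3×3
convolution → batch-norm → ReLU layers with an identity shortcut. When
the incoming channel count differs from the stage width (only at the
first stage) the first shortcut is a 1×1 projection. Downsampling is a
stride-2 3×3 convolution rather than max-pooling; this choice makes the
encoder exactly 20 learnable convolutions deep at the default 4 stages
(4 residual convolutions + 1 downsampling convolution per stage), the
depth `encoder_conv_count()` reports.

**Spatial–channel dual attention.** After each residual stage a
squeeze-and-excitation branch pools every channel to a scalar, passes the
profile through a bottleneck MLP (reduction ratio `r`, floored at width
4), and gates channels with sigmoid weights in (0, 1). The coordinate
attention branch pools along width and height separately, concatenates
the two profiles along the positional axis (this is what makes the shared
1×1 convolution act on an `(H+W)`-long profile), reduces to `C/r`
channels with ReLU, splits back into the two directions and produces
per-row and per-column gates; the input is multiplied by their outer
broadcast product. The two branch outputs are fused by element-wise
addition. The attention block sits in the encoder by default; a config
enum (`sc_placement`) also supports decoder or dual placement, and the
skip connections are tapped *after* attention so the decoder receives
recalibrated features.

**Selectively connected dense pyramid.** The bottleneck runs 3×3
branches at dilations 1, 2, 3 with "same" padding. Branch *l* consumes
the bottleneck input concatenated with the outputs of branches with
strictly smaller dilation — `denseaspp_input_sets()` computes
`S_l = {i : d_i < d_l}` and rejects non-increasing dilation lists, since
a later branch would otherwise need an output that does not yet exist
under sequential processing. A 1×1 projection returns to the bottleneck
width. The receptive-field algebra is `RF = k + (k−1)(d−1)` per branch
(3/5/7) and `K = K1 + K2 − 1` for superimposed fields;
`denseaspp_max_receptive_field()` walks the dense connectivity
(3 ⊕ 5 = 7, then 7 ⊕ 7 = 13) to the maximum of 13 pixels.

The decoder mirrors the encoder with 2×2 transposed convolutions
(bilinear upsampling + convolution available via config), skip
concatenation and two conv–BN–ReLU layers per stage; a 1×1 head emits
3-class logits. Channel widths double per stage from `base_channels`
(64 at full scale, so 1024 at the bottleneck; the test preset uses 8).
Weights are Kaiming-uniform, seeded through the config.

With 448×448 inputs and four halvings the bottleneck is 28×28. Note
that 448/2^4 = 28 exactly; a 32×32 bottleneck would require a 512×512
input, so descriptions quoting 32×32 alongside 448×448 training
resolution are arithmetically inconsistent — this implementation follows
the arithmetic.

### The autodiff engine

No deep-learning framework is assumed: the package carries a small
reverse-mode automatic differentiation engine (`R/autograd.R`,
`R/nn-ops.R`) over `(batch, channel, height, width)` arrays, with
dilated/strided convolution forward and backward passes written in C++
(im2col + GEMM via RcppArmadillo). Nodes are recorded on a tape in
creation order, so the reversed tape is already a topological order for
the backward sweep. Transposed convolution is implemented exactly as the
input-gradient of the strided convolution, which keeps its own gradients
(a forward convolution and a weight-gradient pass) free. Every layer
family is validated against naive loop-based oracles and the whole
network against central finite differences in the test suite.

## Losses

`combined_loss()` is `α·focal + (1−α)·dice` with `α = 0.7` (focal:dice
0.7:0.3), `γ = 2` and `ε = 1e-8`. The focal term computes per-pixel
cross-entropy from softmax probabilities (natural log), sets
`p_t = exp(−CE)` *per pixel* — per-sample focusing, not a batch-mean
shortcut — and averages `(1 − p_t)^γ · CE`. The soft Dice coefficient
pools over all pixels and the batch per class; the loss averages
foreground classes only by default, because including the ~99.9 %
background class would dilute exactly the imbalance correction the
compound loss exists for (`dice_classes = "all_classes"` preserves the
alternative). Gradients with respect to the logits are closed-form
(softmax chain rule for both terms), checked against finite differences.

`alpha_grid_search()` implements the weight-grid protocol at 0.1 spacing
over injected folds with a caller-supplied training routine. On
phantoms it characterises the synthetic task only; it makes no claim
about clinical operating points, which require the real cohort.

## Data, preprocessing and folds

Intensity normalisation z-scores over the *valid region*, interpreted as
strictly positive voxels, since MRI air background is ≈ 0 and the
phantom generator keeps air exactly 0; invalid voxels map to the minimum
normalised value. The population standard deviation is used, so a
two-valued region normalises exactly to ±1 and the valid-region moments
are exactly 0/1 afterwards. Slices are resized with bilinear
interpolation for images and nearest-neighbour for masks (labels must
survive exactly); 512→448 is a downscale, and the resize is skipped
bit-identically when the input is already at target size. Slice
screening retains the lesion-bearing axial slices (third array axis, the
slice-thickness direction) and is applied to *training* data only —
validation and test volumes are predicted and scored in full, because
screening at test time would leak labels.

`make_fold_plan()` shuffles ids under a seed, holds out a third as the
independent test set and splits the remainder into five contiguous
validation blocks: with 150 cases this is the 50-case test set and
80/20 train/validation folds. The actual membership of the original
study's folds is unknowable, so the seeded shuffle is the contract.

## Training protocol

Adam at 1e-4 with batch 16 for up to 1000 epochs at full scale, cosine
annealing from 1e-4 to a 1e-5 floor over a 10 000-step period, early
stopping with 20-epoch patience. The monitored quantity is validation
mean foreground Dice (maximised), computed per epoch by full-volume
inference on the fold's validation cases; the best-scoring weights are
kept. The stopping rule is exposed pure (`early_stop_epoch()`) and fires
exactly `patience` epochs after the best epoch. Batches sample screened
lesion slices uniformly with no augmentation and no oversampling —
imbalance is handled in the loss.

The test preset (`train_config(preset = "test")`) is 64×64 slices,
8 base channels, batch 4, and a 3e-3 step size: with ~500–700 optimiser
steps in a short phantom run, the full-scale 1e-4 rate would not leave
the transient, and 3e-3 is a conventional Adam step for a network this
small. All problem sizes in the shipped tests (64×64×32 phantoms,
28-case cohorts, ≤ 20 epochs) were chosen to exercise convergence while
keeping a single-CPU run in minutes.

## The phantom generator

`generate_case()` emulates the *statistics* of a pre-radiotherapy
T2-weighted head-and-neck cohort, not its anatomy: an ellipsoidal head
of soft tissue (|N(20, 8)| intensities) in exact-zero air on a
0.5×0.5×2.0 mm grid; a total tumor voxel fraction drawn from a
right-skewed (scaled Beta) distribution inside 0.000–0.004; at most one
primary lesion placed near the in-plane centre and nodal lesions placed
laterally — oropharyngeal primaries sit near the midline while nodal
disease lies in the lateral neck levels, and this positional cue is what
lets a 2D network separate the two classes on synthetic data; lesions
are smoothly perturbed ellipsoids (sinusoidally modulated thresholds),
mutually disjoint and confined to the head; per-lesion mean intensities
are uniform in 50–100 and within-lesion standard deviations uniform in
0–50; magnitude-clamped Gaussian noise (sd 2) approximates Rician
acquisition noise inside the head. Per-case seeds are
`base_seed + index − 1`, so cohorts are reproducible and cases distinct.
Default volumes are 64×64×32 so suites stay fast; full 512×512 grids
are accepted.

What passing phantom tests shows — and does not. The generator provides
bright, smoothly bounded, positionally structured lesions with sharp
edges and no partial-volume blur, bias fields, motion artefacts, fat
suppression variability, or anatomically confusable structures
(vessels, lymphoid tissue). Success on phantoms demonstrates that the
architecture, losses, optimisation and evaluation are implemented
correctly and can solve a miniature of the task; it is *not* evidence of
clinical performance, which is why no clinical benchmark value is
claimed anywhere in this package.

## Metrics

`dsc_pair()` returns `NA` (undefined) when both masks are empty — a
Dice of 0 or 1 would be arbitrary there; undefined entries are excluded
from averages and counted. `dsc_agg()` pools intersection and size
counts across cases before the ratio, which is the natural way to score
structures absent from some ground truths; algebraically it is the
`(|gt|+|pred|)`-weighted mean of per-case Dice, an identity the tests
verify numerically. The Hausdorff distance is the symmetric max-min
Euclidean distance between point sets scaled to millimetres. HD95 is
computed volumetrically (spacing is 3D): boundary voxels are those with
a face-adjacent neighbour outside the structure (array edges count as
outside), directed surface-to-surface minimum distances are pooled over
both directions, and the 95th percentile (type-7 quantile) is returned.
The max-form Hausdorff has a closed definition; "95 %" variants differ
across toolkits, and the pooled bidirectional convention used here is
the one common in segmentation challenges.

## Numerical and design notes

* Batch-norm uses biased batch variance, momentum 0.1, eps 1e-5; running
  statistics are used at inference, so inference is deterministic.
* Softmax subtracts the row maximum; `p_t` is floored at 1e-12 before
  the log; for 0 < γ < 1 the modulator's derivative is clamped away from
  the `p_t → 1` singularity.
* The focal/Dice mix is validated as *exactly* affine in α, and focal
  with γ = 0 equals mean cross-entropy to machine precision.
* Fold blocks use contiguous `cut()` splits so sizes differ by at most
  one when the non-test count is not divisible by the fold count.
* Ties in the argmax decode resolve to the first (lowest-label) class.
* `network_config()` floors the attention bottleneck width at 4 so small
  test-preset widths keep a usable reduction MLP.
* Checkpoints (RDS) store the full network config with the weights and
  running statistics, so `load_checkpoint()` rebuilds faithfully.

## Limitations

Purely 2D (no inter-slice context — the known weakness for small
structures and volumetric consistency); CPU-scale only, so full-size
448×448, base-64 training is supported by the code but not practical in
this engine; the phantom cohort cannot stand in for clinical validation;
GFLOP/parameter accounting of the original full-scale design is not a
target because per-stage channel plans beyond the doubling rule are
under-specified in the source material.
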