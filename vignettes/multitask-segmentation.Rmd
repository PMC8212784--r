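---
title: "Multi-task volumetric brain-tumor segmentation: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task volumetric brain-tumor segmentation: models, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvnet)
```

## The problem

Gliomas are segmented on multimodal MRI into three nested regions: the whole
tumor (WT, labels 1/2/4), the tumor core (TC, labels 1/4) and the enhancing
tumor (ET, label 4), following the BraTS convention in which each case carries
four co-registered contrasts — FLAIR, T1, T1-CE and T2 — and an expert label
volume over {0 background, 1 necrosis, 2 edema, 4 enhancing tumor}. Two
properties make this hard for voxel classifiers: extreme class imbalance
(tumor voxels are a small fraction of a 240×240×155 volume) and ragged,
discontinuous predicted boundaries.

`mtvnet` addresses both with a multi-task V-Net: one shared encoder and two
parallel decoders. The first decoder predicts the segmentation mask (softmax
over the 4 label channels). The second regresses, for each foreground class, a
normalized Euclidean distance map (sigmoid over 3 channels). Because the
distance map of a class is smooth inside the class support and exactly zero
outside, forcing the shared features to explain it regularizes the mask
decoder toward compact, smooth-bounded predictions.

## Architecture

The encoder alternates 3×3×3 convolution (batch-norm + ReLU), a multi-depth
fusion block, and 2×2×2 strided-convolution downsampling; filters double at
each of the `encoder_levels` resolution levels. Both decoders mirror the
encoder with 2×2×2 transposed-convolution upsampling and skip connections
from the matching encoder level; the two decoders share no weights and both
receive the same skips.

The multi-depth fusion block mixes signals that have passed through different
numbers of convolutions. With $F(x) = \mathrm{avg}(\mathrm{conv}(\mathrm{conv}(x)),
\mathrm{conv}(x))$ the block computes

$$y = x + \mathrm{avg}\bigl(F_2(F_1(x)), \mathrm{conv}(x)\bigr),$$

where each conv unit is 3×3×3/stride 1 with normalization and ReLU and every
unit has its own weights. The block is shape-preserving and reduces exactly to
the identity when all weights are zero (the residual path), two properties the
test suite checks directly. The composition of the block is stated in the
literature only as prose plus a figure; the algebra above follows the stated
order of operations (two fusion operations of different depth, one extra
convolution on the input, superimpose-and-average, then recombination with the
input as a residual connection). It is isolated behind one function so an
alternative wiring can be swapped in without touching the rest of the model.

Two ablation variants are first-class configurations: *Model I* removes the
fusion blocks (replacing each with a plain second convolution, so the encoder
keeps the conventional two-convolutions-per-level depth), and *Model II* keeps
the architecture but sets the loss weights to $\lambda_1 = 1, \lambda_2 = 0.1$.

Because no deep-learning framework is part of the package's dependency set,
the network is implemented directly: im2col+GEMM 3D convolutions in C++
(RcppArmadillo), a transposed 2×2×2 convolution, per-channel normalization,
and a small reverse-mode autodiff tape in R that records the forward graph and
accumulates gradients through the fan-out of the shared encoder. Every kernel
and the end-to-end gradient are verified against central finite differences in
the test suite.

## Objective

The loss is $L = \lambda_1 L_{mask} + \lambda_2 L_{dist}$ with defaults
$\lambda_1 = \lambda_2 = 1$.

$L_{mask}$ is a weighted categorical focal loss: per voxel,
$-W_t\,(1-p_t)^\gamma \log p_t$ where $p_t$ is the softmax probability of the
true class $t$, $\gamma = 2$, and the class weights are 0.1 for background and
1.0 for all three foreground channels. The focusing factor suppresses the loss
of easy (mostly background) voxels; the background down-weighting further
re-balances the objective. Probabilities are clipped at $10^{-7}$ before the
logarithm. Voxel aggregation is by mean, chosen so the loss magnitude (and
hence the effective learning rate) does not scale with patch size.

$L_{dist}$ is the squared error between the sigmoid outputs and the
ground-truth distance maps. The printed form of this loss in the source
literature is a sum over the voxel domain while its text calls it mean squared
error; the package defaults to the mean (again for patch-size stability) and
exposes the sum under `loss_config(distance_reduction = "sum")`.

The regression target for class $c$ is the *interior* Euclidean distance
transform: 0 outside the class, and inside it the exact distance to the
nearest non-class voxel (separable lower-envelope algorithm, exact for
anisotropic spacing), divided by the per-channel maximum so the deepest
interior voxel maps to 1. The normalization to [0, 1] is forced by the sigmoid
activation of the distance head; it also makes the target scale-invariant
across tumor sizes. An absent class yields an all-zero channel rather than an
error, since low-grade cases can genuinely lack enhancing tumor. Distances are
computed in voxel units by default; a spacing-aware variant is available.

## Training protocol

Adam (β₁ = 0.9, β₂ = 0.999) with an initial learning rate of 1e-4 halved
after every two traversals of the training set, per-traversal shuffling,
loss and mean-Dice logging every 10 steps, and checkpoints plus sample
prediction/ground-truth exports every 1000 steps — these full-scale defaults
are recorded in `train_config()`. Training patches are sampled randomly with
half of the draws forced to intersect tumor (the patch-sampling strategy is
not fixed by the protocol; tumor-biased sampling counters class imbalance),
and distance targets are computed per patch.

The desk-scale profile `desk_train_config()` — the configuration exercised by
the test suite and the acceptance script — keeps the architecture and
objective and reduces capacity and schedule: 3 encoder levels, 4 base
filters, 32³ single-patch steps (300 of them), 20 training cases of 64³
voxels, learning rate 2e-3, and a traversal defined as 20 patches per case.
Under the halve-every-2-traversals rule this keeps the rate constant over
the short run (the first halving would fall at step 800), which at desk
scale converges faster than an early decay. One CPU trains the full model
in about seven minutes. Inference tiles the
volume with overlapping patches (default 32³, overlap 8), averages softmax
probabilities where patches overlap, takes the argmax (ties resolved toward
the lower channel index, deterministically) and maps channel 3 back to label 4.

## Evaluation

Per region (ET/WT/TC after binarization): Dice $2TP/(FN+FP+2TP)$,
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, and the 95th-percentile
Hausdorff distance — the maximum over both directions of the 95th percentile
(linear interpolation) of voxel-to-nearest-voxel distances, computed from the
same exact distance transform. Conventions: both-empty regions score Dice 1;
an empty ground truth with any predicted voxel scores 0; sensitivity and
Hausdorff are *undefined* (not 0) for empty masks and are excluded from
summary means, with the exclusion count reported.

Post-processing implements the enhancing-tumor rule: if fewer than 500 ET
voxels are predicted (strict inequality), all of them are relabeled as
necrosis. Relabeling to necrosis (label 1) is the unique choice that leaves
both the WT and TC binary masks invariant, which the tests verify.

## The phantom generator

Synthetic cases stand in for real BraTS data so the entire pipeline is
testable without downloads. A case is a brain ellipsoid on an exactly-zero
background (emulating skull-stripped inputs) carrying three concentric tumor
ellipsoids — edema, enhancing rim, necrotic core — with one shared center and
per-axis anisotropy jittered ±25% by the seeded generator, so the BraTS
nesting WT ⊇ TC ⊇ ET holds by construction. Default radii are (12, 8, 5)
voxels in a 64³ volume. Intensities are per-tissue means plus Gaussian noise
(sd 10 against tissue means of order 100, i.e. SNR ≈ 10): edema is bright in
FLAIR/T2, the enhancing rim bright in T1-CE, necrosis dark in T1/T1-CE. These
contrast values are conventions that reproduce the qualitative appearance
radiologists use; they are not claims about MRI physics.

What the phantoms deliberately omit — anatomical tissue structure, bias
fields, multi-site intensity variation, irregular infiltrative tumor shapes,
registration artifacts — bounds what passing tests show: they demonstrate
that the implementation is correct and that the model can learn the mapping,
not that it reaches any particular accuracy on real multi-site MRI.

## Numerical choices and edge cases

* Z-score standardization uses whole-volume statistics by default (the
  literal reading of the preprocessing description); brain-only (nonzero
  voxel) statistics are available behind `nonzero_only = TRUE` since the
  voxel set covered by the mean/sd is not specified there. A constant volume
  returns zeros with a warning rather than dividing by zero.
* Standardization is applied to the full volume before patch extraction.
* Normalization layers use batch (current-patch) statistics during training
  and exponentially averaged running statistics (momentum 0.9) at inference.
  Using stored statistics matters at inference time: tiles dominated by
  empty background would otherwise have their nearly constant activations
  rescaled by their own tiny variance, amplifying noise into false-positive
  tumor. Inference is deterministic; an untrained model falls back to
  input statistics.
* In the single-patch training regime the per-patch statistics of
  tumor-biased patches vary enough that a network optimized only under
  batch statistics can behave erratically under the frozen running
  statistics (a train/eval normalization gap that shows up as diffuse
  false-positive tumor). The training loop therefore freezes the running
  statistics after `bn_freeze_step` steps (desk default 150, half the run)
  and continues optimizing against them, so the final phase trains exactly
  the function used at inference. With large-batch training this gap is
  small and the full-scale default leaves freezing off.
* He initialization from a seeded generator; all randomness (weights,
  shuffling, patch sampling, phantom geometry and noise) derives from
  user-visible seeds, and identical seeds give bit-identical runs.
* Patch coordinates are 0-based voxel offsets; the channel axis is last.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.

## Known limitations

Full-scale BraTS training (128×128×64 patches, 16 base filters, 500k steps)
is expressible in the configuration but far outside CPU budgets; the package
makes no claim of reproducing challenge leaderboard accuracy. The two
decoders are fully independent (whether they could share weights is an open
design point), and the fusion-block wiring follows the prose description as
discussed above.
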