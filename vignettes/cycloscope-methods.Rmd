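---
title: "Methods: an annotation-free cell-cycle manifold from one channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an annotation-free cell-cycle manifold from one channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cycloscope)
```

# The problem and the model

The cell cycle progresses through growth (G1), DNA replication (S, with
early/mid/late sub-stages distinguished by the spatial pattern of
replication foci), a second growth phase (G2) and mitosis (M). Supervised
stage classifiers need expert annotations and often multiple fluorescence
channels; `cycloscope` instead learns a latent representation of
single-channel (PCNA-like) image patches with no stage labels, and extracts
staging, key events and cycle timing from that representation afterwards.

The backbone is a VAE-GAN. The encoder (three stride-2 convolutions with
batch normalisation, then dense layers) maps a patch to a diagonal-Gaussian
posterior with `latent_dim` means and log-variances (default 16). The
generator mirrors the encoder with three transposed convolutions and ends in
a sigmoid, honouring the `[0, 1]` pixel contract. The discriminator stacks
four stride-2 convolutions and a realness head; its feature maps after the
fourth convolutional block define the learned similarity metric, a
reconstruction distance that is less pixel-brittle than raw MSE. The
reconstruction objective is the pixel MSE plus `lambda_feat` times the
feature-map MSE; `kl_weight * KL(q || N(0, I))` (KL normalised per latent
dimension) regularises the posterior; the generator additionally receives a
non-saturating adversarial term weighted by `adv_weight`.

Temporal structure enters through the temporal cycle-consistency (TCC)
loss. For two embedded trajectories `U` and `V`, the soft nearest neighbour
of `u_i` in `V` is `v~ = sum_j alpha_j v_j` with
`alpha = softmax(-||u_i - v_j||^2 / tau)`; cycling back,
`beta = softmax(-||v~ - u_k||^2 / tau)` treats each frame of `U` as a class,
and the loss is the mean cross-entropy `-log beta_i`. Frames that occupy the
same cycle position in different cells are pulled together, which aligns the
trajectories along a common cyclic coordinate. Only this classification
variant is implemented; analytic gradients with respect to both sequences
are verified against numerical differentiation in the test suite.

# Training schedule

Training runs in three stages (reconstruction warm-up at
`kl_weight_initial`; linear KL annealing to `kl_weight_final` over the first
half of stage 2, preventing posterior collapse; TCC fine-tuning at
`tcc_weight`), each with three Adam optimisers (encoder, generator,
discriminator) at a common learning rate. Every `checkpoint_every` epochs
the total stage loss is evaluated on a held-out validation split (a fraction
of training trajectories, at least one cell); the best parameter snapshot is
kept, and a stage stops early after `early_stop_patience` unimproved
checkpoints, restoring the best snapshot. During stage 3, one pair of
distinct trajectories is sampled per minibatch; full sequences are used up
to `tcc_window` frames, longer ones contribute a random contiguous window.

Defaults follow standard practice for this model family: learning rate
`1e-4`, `kl_weight_initial = 1e-3`, `kl_weight_final = 1`,
`lambda_feat = 1`, `tcc_weight = 0.1`, batch 32, checkpoints every 10
epochs. Two engineering choices matter at small scale and are deliberate:

* `adv_weight` (default 0.01) scales the *generator's* adversarial gradient
  only. Unscaled, that gradient is roughly two orders of magnitude larger
  than the pixel-reconstruction gradient at these patch sizes and the
  generator chases the discriminator instead of reconstructing. The
  discriminator itself always trains at full strength.
* The encoder's log-variance head is initialised at -4 so the posterior
  starts near-deterministic; otherwise unit-scale sampling noise swamps the
  latent signal early and evaluation-mode decoding (which uses the mean)
  diverges from training behaviour.

Batch-norm running statistics are recomputed from one full pass over the
training frames before every validation ("precise" batch norm); with few
cells the exponential moving average lags the weights badly enough to make
evaluation-mode forward passes meaningless.

# The synthetic-movie generator

The generator emulates the data conventions of single-channel PCNA
live-cell imaging: square patches with a centred nucleus, `[0, 1]`
intensities quantised to a 16-bit grid, 5.9-minute frame intervals, and
trajectories roughly synchronised just before mitosis (initial phase
0.85 +/- 0.03). Phase advances by `1/period_frames` per frame with optional
multiplicative jitter; a wrap past 1 is a division event and resets the
cell. Appearance is a continuous function of phase: nucleus radius grows
through interphase; brightness keyframes rise from a dim G1 through a late-S
maximum, dip in G2, and jump during mitotic condensation (radius shrinks to
about half within the first 40% of M); replication foci fade in at the
G1/S boundary, evolve from many-small to few-large-bright, and fade out into
G2. Continuity matters: stepwise per-stage styles would produce isolated
appearance clusters rather than the continuous cyclic manifold real PCNA
movies trace, and the trajectory-level analytics depend on that geometry.
Defaults: patch 64 px, stage fractions G1 0.35, early S 0.12, mid S 0.12,
late S 0.12, G2 0.21, M 0.08 (typical transformed-cell-line proportions,
configurable, not asserted as fact), additive noise sigma 0.02, photobleach
5e-4 per frame.

What the generator does *not* emulate: segmentation/tracking errors,
neighbouring cells entering the crop, uneven illumination, cell-to-cell
morphological heterogeneity beyond foci placement, and apoptosis or cycle
arrest. Passing tests on synthetic movies therefore demonstrates that the
machinery recovers a cyclic appearance process when one is present, not that
it is robust to every real-data artifact.

# Projection and orientation

The trained latent space is viewed in 2-D with a linear projector fit on
training latents only and reused, unchanged, on held-out cells. Two modes
exist. Plain principal components are the fallback; their orientation is
arbitrary per fit, so `orient_projection()` applies the rigid in-plane
rotation (sign flip in the 1-D case) that puts reference frames — division
or M-called frames — at the minimum pole of axis 1.

The pipeline's default is the *division-anchored* mode: axis 1 is the latent
direction whose projection best tracks the rank of each training frame's
temporal distance to its nearest division event (least squares on ranks),
and axis 2 is the leading principal component of the residual variance.
Division events are observable from tracking (a cell visibly splits) and
carry no stage annotation, so this remains self-supervised in the same sense
as the temporal loss itself. The motivation is geometric: nonlinear
neighbourhood embeddings tend to place the mitotic cluster at an extreme of
the first axis, but a variance-ranked linear basis has no reason to — the
latent cycle is strongly anisotropic (the G1-to-late-S appearance contrast
dominates) and mitosis, a brief transition through intermediate appearances,
sits inside the projected loop. Anchoring recovers the useful property
(mitosis at the axis-1 minimum, monotone rise with cycle distance from
division) within a linear, deterministic, exactly out-of-sample projector.

# Staging

Pooled training latents are clustered with an 8-component full-covariance
Gaussian mixture (via `mclust`, with a conjugate prior for numerical
stability; deterministic model-based initialisation). Eight components
deliberately over-segment six biological stages: surplus components capture
sub-populations and are merged after naming. Naming is by majority vote of
post hoc labels within each component — labels are used only here and in
evaluation, never during training — with ties going to the globally more
frequent stage, then canonical order. A frame's call is the stage of its
argmax-responsibility component, making the classifier a total function on
latent space.

The G1-G2 constraint exploits the cycle's order: growth stages flank S, so
a G1 call at or after the inferred late-S time must be G2 and a G2 call
before it must be G1 (a call exactly at the late-S frame counts as after).
The late-S time comes from the trajectory analytics (the highest in-cycle
peak of the smoothed axis-1 curve); when a recording spans several cycles
the rule is applied per segment between consecutive M troughs, and segments
without a late-S assignment are left untouched. With the true late-S
midpoint the correction provably never lowers accuracy (tested); with an
*inferred* late-S it usually helps but can slightly hurt when the peak is
displaced — both raw and constrained accuracies are always reported.

# Trajectory analytics

Axis-1 curves are smoothed with a cubic smoothing spline
(`smoothing_factor` is the spline's smoothing parameter; 0 interpolates,
default 0.6), axis-2-style period curves with a centred 10-frame running
average (edge-truncated windows). Extrema are interior local maxima/minima
filtered by topographic prominence; `find_extrema()` defaults to a quarter
of the curve range. Key stages read off the curve: the two *lowest* troughs
are consecutive mitoses bounding a full cycle; within it the highest peak is
late S, the first peak (when distinct) G1, and the trough between them early
S; inflection frames (zero crossings of the second difference) annotate
transitions. The cycle duration is the spacing of the two *most prominent*
troughs times the frame interval. Both event assignment and duration
estimation consider all interior extrema (prominence threshold 0) because a
division trough near the start or end of a recording has edge-clipped
prominence yet is exactly the feature being sought; the selection rules
("two lowest", "two most prominent") do the filtering. In the pipeline, the
duration is estimated from the axis that carries the once-per-cycle sudden
drop at division: axis 1 in anchored mode, axis 2 otherwise.

# Scaled-down study sizes

The package's own evaluation (`study_config_small()`, used by the test suite
and `scripts/acceptance.R`) runs at desk scale: 16 cells, 64 frames at
5.9 min, a 48-frame (4.72 h) cycle, 32 x 32 patches, an 8-d latent space
with narrow conv stacks (8/16/32 channels; discriminator 8/16/32/64), 60%
of cells for training with one validation cell, and at most 80 epochs per
stage with early stopping. Compared with the full-scale defaults the study
uses a 20x larger learning rate (2e-3) and a down-weighted similarity term
(`lambda_feat = 0.03`) — with 10x fewer epochs the optimiser needs larger
steps, and a narrow, briefly-trained discriminator makes a noisy metric —
and `tcc_weight = 0.5`, at which the stage-3 alignment loss actually
converges (about 3.7 to 0.6) at this scale.

# Numerical choices and degenerate inputs

Log-variances are clamped to [-8, 8] (gradients masked outside). Mixture
responsibilities, softmaxes and discriminator probabilities are guarded
against under/overflow (max-shifted exponentials; probabilities clipped to
[1e-7, 1 - 1e-7]). A constant series smooths to itself; a monotone curve
yields no extrema and key-stage assignment returns a partial result with a
warning rather than failing; fewer than two troughs give an `NA` duration.
Empty mixture components map to the globally most frequent stage with a
warning. Trajectory datasets round-trip bit-exactly through 16-bit TIFF
because rendered intensities live on the 16-bit grid. All randomness flows
from explicit seeds (per-cell generator streams derive from the master
seed), and model checkpoints reload with bit-identical forward passes.

# Known limitations

The networks run on CPU BLAS in R: fine at study scale (a full three-stage
run takes a few minutes), not intended for full-resolution datasets with
hundreds of cells. The linear projector, even anchored, cannot fully unroll
a strongly non-convex latent cycle the way nonlinear embeddings can; the
anchored axis is tent-shaped over a cycle, so the G1-peak / early-S-trough
sub-structure of the event assignment is often absent and only mitoses and
late S are called. Stage-boundary calls inherit the mixture model's
confusions between visually similar neighbours (mid vs late S above all).
The duration estimator assumes at least two divisions inside the recording;
cells imaged for less than one full cycle are reported as `NA`.
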