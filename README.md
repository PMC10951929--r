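# cycloscope

Annotation-free learning of a cell-cycle manifold from single-channel
live-cell movies.

Live-cell studies of the cell cycle usually depend on expert stage
annotations or dedicated multi-channel reporter systems (such as the
two-probe FUCCI setup). `cycloscope` implements a different route for users
with only a single fluorescence channel — for example EGFP-PCNA, whose
punctate replication-foci pattern changes characteristically through S
phase. A generative model is trained on ordered single-cell image patches
without any stage labels, and the stages, key cycle events and the cycle
duration are read off the learned latent space afterwards.

## The model

Each frame `x` (a square patch scaled to [0, 1]) is encoded as a diagonal
Gaussian posterior `q(z | x) = N(mu(x), diag(sigma^2(x)))` in a
16-dimensional latent space. A shared generator/decoder `G` reconstructs the
frame from sampled `z`, and a convolutional discriminator `D` both drives an
adversarial objective and supplies a *learned similarity metric*: the mean
squared distance between its intermediate feature maps of `x` and `G(z)`.
Training minimises

```
L = MSE(x, G(z)) + lambda_f * MSE(f_D(x), f_D(G(z)))
    + w_KL * KL(q(z|x) || N(0, I)) + w_adv * L_GAN + w_TCC * L_TCC
```

in three stages: (1) reconstruction warm-up with a low KL weight, (2) linear
KL-weight annealing to structure the latent space, and (3) temporal
cycle-consistency (TCC) fine-tuning. The TCC loss aligns pairs of
trajectories: the soft nearest neighbour of frame `u_i` in a second sequence
`V` (`alpha_j = softmax_j(-||u_i - v_j||^2)`, `v~ = sum_j alpha_j v_j`) must
classify back to frame `i` among the frames of `U`
(`beta = softmax_k(-||v~ - u_k||^2)`, loss `-log beta_i`).

Downstream, per-frame latent means are clustered with an 8-component
Gaussian mixture, components are named by majority vote against post hoc
labels and merged per stage, and a temporal constraint reclassifies growth
stages: any G1 call at or after the inferred late-S time becomes G2, any G2
call before it becomes G1. Single-cell trajectories projected to 2-D yield
key stage events from their peaks and troughs, and the cell-cycle duration
from the spacing of the curve's two most prominent troughs.

A bundled synthetic-movie generator (growing nucleus, phase-dependent
PCNA-like foci, mitotic condensation, known phase/stage/period ground truth)
makes the whole pipeline testable end to end.

All neural-network machinery (stride-2 convolutions via im2col, transposed
convolutions as exact adjoints, batch normalisation, Adam, manual
backpropagation) is implemented in the package on top of R's BLAS.

## Worked example

```r
library(cycloscope)

# a desk-scale study: 16 synthetic cells, 64 frames at 5.9 min, 48-frame cycle
res <- run_pipeline(study_config_small(seed = 1), n_runs = 1)
glance(res)
#> # A tibble: 1 x 8
#>   n_runs accuracy_raw_mean accuracy_raw_sd accuracy_constrained_mean ...
#> 1      1              85.2              NA                      81.5

run <- res$runs[[1]]
run$durations
#> # A tibble: 6 x 3
#>   cell_id  duration_hours true_hours
#> 1 cell_006           4.82       4.72
#> 2 cell_008           4.82       4.72
#> ...
```

`85.2` is the held-out frame-level staging accuracy (percent) of the
mixture-model classifier on the learned manifold; `duration_hours` is each
held-out cell's estimated cycle time against the generator's true `4.72` h —
here every estimate lands within 2 % of the truth. Lower-level pieces are
ordinary functions:

```r
ds    <- simulate_dataset(synthetic_config(patch_size = 32, n_frames = 64,
                                           period_frames = 48), n_cells = 16)
model <- train_manifold(ds[1:10], training_schedule(epochs_per_stage = 80))
lat   <- embed_dataset(model, ds[11:16])
```

A thin command-line front end is installed with the package
(`system.file("scripts", "cycloscope", package = "cycloscope")`), with
`simulate` and `run-all` subcommands writing TIFF/CSV/JSON artifacts.

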