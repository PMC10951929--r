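# Shared tiny fixtures, built in code. The smoke model is trained once per
# test run at toy scale and reused by the model/manifold tests.

tiny_synth_config <- function(seed = 11L, n_frames = 24L, patch = 16L) {
  synthetic_config(patch_size = patch, n_frames = n_frames,
                   period_frames = 16, frame_interval = 5.9,
                   period_jitter = 0, noise_sigma = 0.02, seed = seed)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_synth_config(), 4)
    cache
  }
})

tiny_schedule <- function(epochs = 4L, stages = 1:3, seed = 21L) {
  training_schedule(epochs_per_stage = epochs, lr = 1e-3,
                    lambda_feat = 0.03, adv_weight = 0.01,
                    checkpoint_every = 2, early_stop_patience = 10,
                    batch_size = 16, tcc_window = 12,
                    stages = stages, seed = seed)
}

smoke_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_manifold(tiny_dataset(), tiny_schedule(),
                               latent_dim = 4, enc_channels = c(4, 6, 8),
                               dense_units = 16,
                               disc_channels = c(4, 6, 8, 8))
    }
    cache
  }
})

# latents drawn from well-separated Gaussians with stage names attached
gaussian_stage_latents <- function(n_per = 60, dim = 16, sep = 20,
                                   stages = c("G1", "earlyS", "lateS", "G2", "M"),
                                   seed = 5L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(length(stages) * dim), length(stages))
  centers <- sep * centers / sqrt(rowSums(centers^2))
  Z <- do.call(rbind, lapply(seq_along(stages), function(i) {
    matrix(stats::rnorm(n_per * dim, 0, 1), n_per) +
      rep(centers[i, ], each = n_per)
  }))
  list(latents = Z, stage = rep(stages, each = n_per))
}
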