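test_that("phase_to_stage partitions the unit interval in canonical order", {
  expect_identical(phase_to_stage(0), "G1")
  expect_identical(phase_to_stage(0.999), "M")
  u <- rep(1 / 6, 6)
  names(u) <- CYCLE_STAGES
  expect_identical(phase_to_stage(0.5, u), "lateS")

  # every phase maps to exactly one stage; boundaries are half-open [lo, hi)
  fr <- synthetic_config()$stage_fractions
  lo <- c(0, cumsum(fr))[1:6]
  expect_identical(unname(phase_to_stage(lo, fr)), CYCLE_STAGES)
  expect_identical(unname(phase_to_stage(lo + 1e-12, fr)), CYCLE_STAGES)
  set.seed(1)
  ph <- runif(500)
  expect_true(all(phase_to_stage(ph, fr) %in% CYCLE_STAGES))

  expect_error(phase_to_stage(1), "\\[0, 1\\)")
  expect_error(phase_to_stage(-0.01), "\\[0, 1\\)")
})

test_that("rendered patches are deterministic, bounded, and M outshines G1", {
  cfg <- synthetic_config(patch_size = 32, noise_sigma = 0)
  set.seed(3); a <- render_cell(0.4, cfg)
  set.seed(3); b <- render_cell(0.4, cfg)
  expect_identical(a, b)

  for (ph in c(0, 0.3, 0.55, 0.8, 0.95)) {
    img <- render_cell(ph, cfg)
    expect_gte(min(img), 0)
    expect_lte(max(img), 1)
    expect_identical(dim(img), c(32L, 32L))
  }

  # mitotic condensation concentrates signal: brighter on average than G1
  m_mid <- 1 - 0.5 * cfg$stage_fractions[["M"]]
  expect_gt(mean(render_cell(m_mid, cfg)), mean(render_cell(0.1, cfg)))
})

test_that("simulated trajectories carry consistent ground truth", {
  cfg <- synthetic_config(patch_size = 16, n_frames = 255, period_frames = 200,
                          period_jitter = 0)
  set.seed(9)
  tr <- simulate_trajectory(cfg)
  expect_s3_class(tr, "cell_trajectory")
  expect_identical(dim(tr$images), c(16L, 16L, 255L))
  expect_gte(length(tr$truth$division_frames), 1)
  expect_identical(tr$truth$stage,
                   phase_to_stage(tr$truth$phase, cfg$stage_fractions))
  expect_true(all(tr$truth$phase >= 0 & tr$truth$phase < 1))

  # with no jitter, two divisions are exactly one period apart
  cfg2 <- synthetic_config(patch_size = 16, n_frames = 2 * 24,
                           period_frames = 24, period_jitter = 0)
  set.seed(2)
  tr2 <- simulate_trajectory(cfg2)
  divs <- tr2$truth$division_frames
  expect_gte(length(divs), 2)
  expect_equal(diff(divs[1:2]) * cfg2$frame_interval,
               tr2$truth$true_period_minutes)

  set.seed(7); x1 <- simulate_trajectory(cfg)
  set.seed(7); x2 <- simulate_trajectory(cfg)
  expect_identical(x1$images, x2$images)
})

test_that("datasets are reproducible with distinct per-cell streams", {
  cfg <- tiny_synth_config(seed = 42L, n_frames = 8L)
  d1 <- simulate_dataset(cfg, 3)
  d2 <- simulate_dataset(cfg, 3)
  expect_identical(d1[[2]]$images, d2[[2]]$images)
  expect_false(identical(d1[[1]]$images, d1[[2]]$images))
  expect_identical(vapply(d1, function(x) x$cell_id, character(1)),
                   c("cell_001", "cell_002", "cell_003"))
})

test_that("stage label marginals track the configured fractions", {
  cfg <- synthetic_config(patch_size = 16, n_frames = 60, period_frames = 48,
                          period_jitter = 0.05, initial_phase_sd = 0.4,
                          seed = 8L)
  ds <- simulate_dataset(cfg, 30)
  stages <- unlist(lapply(ds, function(tr) tr$truth$stage))
  freq <- table(factor(stages, levels = CYCLE_STAGES)) / length(stages)
  # binomial sampling tolerance at n = 1800 plus phase-coverage wobble
  for (s in CYCLE_STAGES) {
    p <- cfg$stage_fractions[[s]]
    expect_lt(abs(freq[[s]] - p), 4 * sqrt(p * (1 - p) / length(stages)) + 0.03)
  }
})

test_that("the manifest tabulates frames tidily", {
  ds <- tiny_dataset()
  mf <- trajectory_manifest(ds)
  expect_s3_class(mf, "tbl_df")
  expect_identical(nrow(mf), 4L * 24L)
  expect_true(all(c("cell_id", "frame", "time_min", "phase", "stage",
                    "division_flag") %in% names(mf)))
  expect_identical(sum(mf$division_flag),
                   length(unlist(lapply(ds, function(t) t$truth$division_frames))))
})
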