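test_that("the KL annealing weight ramps linearly and saturates", {
  s <- training_schedule(epochs_per_stage = 200, kl_weight_initial = 0,
                         kl_weight_final = 1, kl_anneal_epochs = 100)
  expect_equal(kl_annealing_weight(0, s), 0)
  expect_equal(kl_annealing_weight(50, s), 0.5)
  expect_equal(kl_annealing_weight(100, s), 1)
  expect_equal(kl_annealing_weight(500, s), 1)
  w <- vapply(0:200, kl_annealing_weight, numeric(1), schedule = s)
  expect_true(all(diff(w) >= 0))
  expect_equal(kl_annealing_weight(50, s, stage = 1), s$kl_weight_initial)
  expect_equal(kl_annealing_weight(0, s, stage = 3), s$kl_weight_final)
})

test_that("total loss switches terms by stage and its breakdown adds up", {
  s <- training_schedule(epochs_per_stage = 10, tcc_weight = 0.3)
  terms <- list(pixel = 0.2, feature = 0.1, kl = 4, adv_gen = 0.7, tcc = 1.5)
  t2 <- total_loss(2, terms, s, epoch = 2, latent_dim = 8)
  t3 <- total_loss(3, terms, s, epoch = 2, latent_dim = 8)
  expect_equal(t3$total - t3$breakdown[["tcc"]],
               total_loss(3, c(terms[-5], tcc = 0), s, 2, 8)$total)
  expect_equal(sum(t2$breakdown), t2$total)
  expect_equal(sum(t3$breakdown), t3$total)
  expect_equal(t2$breakdown[["tcc"]], 0)

  # with every auxiliary weight off and perfect reconstruction, nothing is left
  s0 <- training_schedule(epochs_per_stage = 10, kl_weight_initial = 0,
                          kl_weight_final = 0, lambda_feat = 0, adv_weight = 0,
                          tcc_weight = 0)
  z <- total_loss(1, list(pixel = 0, feature = 1, kl = 3, adv_gen = 2, tcc = 1),
                  s0, 0, 8)
  expect_equal(z$total, 0)
  expect_error(total_loss(4, terms, s), "stage")
})

test_that("with auxiliary terms disabled the objective is the analytic ELBO", {
  s0 <- training_schedule(epochs_per_stage = 10, lambda_feat = 0,
                          adv_weight = 0, kl_weight_initial = 0.5,
                          kl_weight_final = 0.5)
  terms <- list(pixel = 0.12, feature = 0.4, kl = 6, adv_gen = 3, tcc = 2)
  got <- total_loss(1, terms, s0, 0, latent_dim = 4)
  expect_equal(got$total, 0.12 + 0.5 * 6 / 4)
})

test_that("staged training runs, logs every epoch and is reproducible", {
  m <- smoke_model()
  lg <- m$training_log
  expect_identical(nrow(lg), 12L)            # 4 epochs x 3 stages
  expect_identical(unique(lg$stage), 1:3)
  expect_true(all(is.finite(lg$total)))
  expect_identical(m$stage_reached, 3L)
  expect_true(all(c("pixel", "kl", "adv_gen", "adv_disc", "tcc") %in% names(lg)))
  expect_true(all(lg$tcc[lg$stage < 3] == 0))
  expect_true(all(lg$tcc[lg$stage == 3] > 0))

  # same seed, same data: identical loss trace
  m2 <- train_manifold(tiny_dataset(), tiny_schedule(),
                       latent_dim = 4, enc_channels = c(4, 6, 8),
                       dense_units = 16, disc_channels = c(4, 6, 8, 8))
  expect_equal(m$training_log$total, m2$training_log$total)
})

test_that("KL weight is monotone non-decreasing across stage 2 of a real run", {
  lg <- smoke_model()$training_log
  w2 <- lg$kl_weight[lg$stage == 2]
  expect_true(all(diff(w2) >= 0))
})

test_that("training refuses TCC with a single trajectory", {
  expect_error(train_manifold(tiny_dataset()[1], tiny_schedule()),
               "at least 2 trajectories")
  # but a single trajectory is fine when stage 3 is disabled
  expect_silent({
    m <- train_manifold(tiny_dataset()[1:2],
                        tiny_schedule(epochs = 2L, stages = 1L),
                        latent_dim = 4, enc_channels = c(4, 6, 8),
                        dense_units = 16, disc_channels = c(4, 6, 8, 8))
  })
})

test_that("broom-style accessors summarise a fitted model", {
  m <- smoke_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "value") %in% names(td)))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$stage_reached, 3L)
  expect_identical(gl$epochs_run, 12L)
})
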