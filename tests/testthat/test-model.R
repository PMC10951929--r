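test_that("encoding is finite, deterministic and batch-invariant", {
  m <- manifold_model(patch_size = 16, latent_dim = 4,
                      enc_channels = c(4, 6, 8), dense_units = 16,
                      disc_channels = c(4, 6, 8, 8), seed = 3L)
  zero <- matrix(0, 16, 16)
  p <- encode(m, zero)
  expect_true(all(is.finite(p$mu)), all(is.finite(p$logvar)))
  expect_identical(dim(p$mu), c(1L, 4L))

  set.seed(1)
  imgs <- array(runif(16 * 16 * 5), c(16, 16, 5))
  p1 <- encode(m, imgs)
  p2 <- encode(m, imgs)
  expect_identical(p1, p2)

  # batched encoding equals per-image encoding in evaluation mode
  single <- t(vapply(1:5, function(i) encode(m, imgs[, , i])$mu[1, ],
                     numeric(4)))
  expect_equal(unname(p1$mu), unname(single), tolerance = 1e-12)

  expect_error(encode(m, matrix(0, 8, 8)), "16x16")
})

test_that("latent sampling follows the reparameterisation", {
  post <- list(mu = matrix(c(1, -2, 0.5), 1), logvar = matrix(rep(-20, 3), 1))
  z <- sample_latent(post)
  expect_equal(as.numeric(z), c(1, -2, 0.5), tolerance = 1e-4)

  set.seed(5); z1 <- sample_latent(list(mu = matrix(0, 1, 3),
                                        logvar = matrix(0, 1, 3)))
  set.seed(5); z2 <- sample_latent(list(mu = matrix(0, 1, 3),
                                        logvar = matrix(0, 1, 3)))
  expect_identical(z1, z2)

  # Monte-Carlo mean matches mu within 4 standard errors
  set.seed(6)
  n <- 10000
  post <- list(mu = matrix(2, n, 1), logvar = matrix(log(0.25), n, 1))
  zs <- sample_latent(post)
  se <- 0.5 / sqrt(n)
  expect_lt(abs(mean(zs) - 2), 4 * se)
})

test_that("decoding honours the pixel range and latent-dim contract", {
  m <- manifold_model(patch_size = 16, latent_dim = 4,
                      enc_channels = c(4, 6, 8), dense_units = 16,
                      disc_channels = c(4, 6, 8, 8), seed = 3L)
  set.seed(2)
  z <- matrix(rnorm(3 * 4, sd = 3), 3)
  imgs <- decode(m, z)
  expect_gte(min(imgs), 0)
  expect_lte(max(imgs), 1)
  expect_identical(decode(m, z), imgs)
  expect_error(decode(m, matrix(0, 1, 7)), "4 columns")
})

test_that("discriminator output and learned-similarity features behave", {
  m <- manifold_model(patch_size = 16, latent_dim = 4,
                      enc_channels = c(4, 6, 8), dense_units = 16,
                      disc_channels = c(4, 6, 8, 8), seed = 3L)
  d <- discriminate(m, matrix(0, 16, 16))
  expect_true(is.finite(d$realness) && d$realness > 0 && d$realness < 1)
  expect_true(all(is.finite(d$features)))

  set.seed(4)
  x <- matrix(runif(256), 16, 16)
  f1 <- discriminate(m, x)$features
  f2 <- discriminate(m, x)$features
  expect_identical(f1, f2)

  # identical inputs give zero learned-similarity distance
  rl <- reconstruction_loss(m, x, x)
  expect_equal(rl$total, 0)
  expect_equal(rl$feature, 0)
})

test_that("KL divergence matches the closed form and a sampling oracle", {
  expect_equal(kl_divergence(list(mu = matrix(0, 1, 4),
                                  logvar = matrix(0, 1, 4))), 0)
  expect_equal(kl_divergence(list(mu = matrix(1), logvar = matrix(0))), 0.5)

  set.seed(11)
  for (i in 1:5) {
    mu <- rnorm(3); lv <- rnorm(3, sd = 0.5)
    kl <- kl_divergence(list(mu = matrix(mu, 1), logvar = matrix(lv, 1)))
    expect_gte(kl, 0)
    # Monte-Carlo E[log q(z) - log p(z)], z ~ q
    n <- 1e5
    z <- matrix(rnorm(n * 3), n, 3) * rep(exp(lv / 2), each = n) +
      rep(mu, each = n)
    lq <- rowSums(dnorm(z, mean = rep(mu, each = n),
                        sd = rep(exp(lv / 2), each = n), log = TRUE))
    lp <- rowSums(dnorm(z, log = TRUE))
    diffs <- lq - lp
    se <- sd(diffs) / sqrt(n)
    expect_lt(abs(kl - mean(diffs)), 3 * se + 1e-8)
  }
})

test_that("reconstruction loss combines pixel and feature terms", {
  m <- manifold_model(patch_size = 16, latent_dim = 4,
                      enc_channels = c(4, 6, 8), dense_units = 16,
                      disc_channels = c(4, 6, 8, 8), seed = 3L)
  set.seed(8)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(runif(256), 16, 16)
  full <- reconstruction_loss(m, x, y)
  pix <- reconstruction_loss(m, x, y, lambda_feat = 0)
  expect_equal(pix$total, mean((x - y)^2))
  expect_gt(full$total, pix$total)
  # symmetry of both terms
  swapped <- reconstruction_loss(m, y, x)
  expect_equal(full$total, swapped$total)
  expect_error(reconstruction_loss(m, x, matrix(0, 8, 8)), "16x16")
})

test_that("adversarial losses match their closed forms", {
  half <- adversarial_losses(rep(0.5, 4), rep(0.5, 4))
  expect_equal(half$disc, 2 * log(2))
  expect_equal(half$gen, log(2))
  perfect <- adversarial_losses(1, 0)
  expect_lt(perfect$disc, 1e-5)
  fooled <- adversarial_losses(0.5, 1)
  expect_lt(fooled$gen, 1e-5)
})

test_that("checkpoints reload with bit-identical forward passes", {
  m <- smoke_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  img <- tiny_dataset()[[1]]$images
  expect_identical(encode(m, img), encode(m2, img))
  expect_identical(decode(m, matrix(0.3, 1, 4)), decode(m2, matrix(0.3, 1, 4)))
})
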