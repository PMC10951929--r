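# VAE-GAN for cell-image manifolds: encoder to a diagonal-Gaussian latent,
# generator/decoder shared with the GAN, and a discriminator whose fourth
# convolutional feature map defines the learned similarity metric.

LOGVAR_CLAMP <- 8

build_encoder <- function(patch_size, latent_dim, channels, dense_units) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- patch_size / 8L
  head <- layer_dense(dense_units, 2L * latent_dim)
  # start the posterior near-deterministic (sigma ~ exp(-2)) so early
  # reconstruction is not swamped by sampling noise
  head$params$b[latent_dim + seq_len(latent_dim)] <- -4
  list(layer_conv(1L, c1), layer_bn(c1), layer_act("lrelu"),
       layer_conv(c1, c2), layer_bn(c2), layer_act("lrelu"),
       layer_conv(c2, c3), layer_bn(c3), layer_act("lrelu"),
       layer_flatten(),
       layer_dense(fm * fm * c3, dense_units), layer_act("lrelu"),
       head)
}

build_decoder <- function(patch_size, latent_dim, channels, dense_units) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- patch_size / 8L
  list(layer_dense(latent_dim, dense_units), layer_act("relu"),
       layer_dense(dense_units, fm * fm * c3), layer_act("relu"),
       layer_unflatten(fm, fm, c3),
       layer_convt(c3, c2), layer_bn(c2), layer_act("relu"),
       layer_convt(c2, c1), layer_bn(c1), layer_act("relu"),
       layer_convt(c1, 1L), layer_act("sigmoid"))
}

build_discriminator <- function(patch_size, channels) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]; c4 <- channels[4]
  fm <- patch_size / 16L
  net <- list(layer_conv(1L, c1), layer_act("lrelu"),
              layer_conv(c1, c2), layer_bn(c2), layer_act("lrelu"),
              layer_conv(c2, c3), layer_bn(c3), layer_act("lrelu"),
              layer_conv(c3, c4), layer_bn(c4), layer_act("lrelu"),
              layer_flatten(),
              layer_dense(fm * fm * c4, 1L), layer_act("sigmoid"))
  attr(net, "feature_index") <- 11L  # activation after the 4th conv block
  net
}

#' Create an untrained cell-cycle manifold model
#'
#' Builds the three networks of the VAE-GAN: an encoder mapping patches to a
#' diagonal-Gaussian posterior (`latent_dim` means and log-variances), a
#' generator/decoder mirroring it with transposed convolutions and a sigmoid
#' output honouring the `[0, 1]` pixel contract, and a discriminator whose
#' intermediate feature maps provide the learned similarity metric.
#'
#' @param patch_size Input patch side; must be one of 16, 32, 64, 128.
#' @param latent_dim Latent dimensionality (default 16).
#' @param enc_channels Encoder conv channel widths (3 stride-2 layers).
#' @param dense_units Width of the dense layer between conv stack and latent.
#' @param disc_channels Discriminator conv channel widths (4 stride-2 layers
#'   before the realness head).
#' @param seed Seed for weight initialisation.
#' @return A `manifold_model` object.
#' @examples
#' m <- manifold_model(patch_size = 16, latent_dim = 4,
#'                     enc_channels = c(4, 8, 8), dense_units = 16,
#'                     disc_channels = c(4, 8, 8, 8))
#' @export
manifold_model <- function(patch_size = 64, latent_dim = 16,
                           enc_channels = c(32, 64, 128),
                           dense_units = 256,
                           disc_channels = c(32, 64, 128, 256),
                           seed = 1L) {
  if (!patch_size %in% c(16L, 32L, 64L, 128L)) {
    stop("patch_size must be one of 16, 32, 64, 128")
  }
  stopifnot(latent_dim >= 1, length(enc_channels) == 3, length(disc_channels) == 4)
  set.seed(seed)
  structure(list(encoder = build_encoder(patch_size, latent_dim, enc_channels,
                                         dense_units),
                 decoder = build_decoder(patch_size, latent_dim, enc_channels,
                                         dense_units),
                 discriminator = build_discriminator(patch_size, disc_channels),
                 patch_size = as.integer(patch_size),
                 latent_dim = as.integer(latent_dim),
                 enc_channels = enc_channels,
                 dense_units = dense_units,
                 disc_channels = disc_channels,
                 stage_reached = 0L,
                 seed = as.integer(seed)),
            class = "manifold_model")
}

#' @export
print.manifold_model <- function(x, ...) {
  cat("VAE-GAN manifold model: ", x$patch_size, "x", x$patch_size,
      " px -> ", x$latent_dim, "-d latent; training stage reached: ",
      x$stage_reached, "\n", sep = "")
  invisible(x)
}

# Coerce (H,W) matrix, (H,W,N) stack or (H,W,N,1) array to the engine's
# (H, W, N, C=1) batch layout (a free reshape for single-channel stacks).
as_batch <- function(images, patch_size) {
  d <- dim(images)
  if (is.null(d)) stop("images must be a matrix or array")
  if (length(d) == 2) {
    dim(images) <- c(d[1], d[2], 1L, 1L)
  } else if (length(d) == 3) {
    dim(images) <- c(d[1], d[2], d[3], 1L)
  }
  d <- dim(images)
  if (d[1] != patch_size || d[2] != patch_size || d[4] != 1L) {
    stop("image batch must be ", patch_size, "x", patch_size,
         " single-channel (got ", paste(d, collapse = "x"), ")")
  }
  images
}

#' Encode image patches to their Gaussian posterior
#'
#' Runs the encoder in evaluation mode (batch-norm running statistics), so the
#' output is deterministic and batch-invariant.
#'
#' @param model A `manifold_model`.
#' @param images Patch matrix, `(H, W, N)` stack or `(H, W, 1, N)` array with
#'   values in `[0, 1]`.
#' @return List with `mu` and `logvar`, each an `N x latent_dim` matrix.
#' @export
encode <- function(model, images) {
  x <- as_batch(images, model$patch_size)
  out <- net_forward(model$encoder, x, training = FALSE)$out
  L <- model$latent_dim
  mu <- out[, seq_len(L), drop = FALSE]
  logvar <- out[, L + seq_len(L), drop = FALSE]
  logvar <- pmin(pmax(logvar, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("encoder produced non-finite posterior parameters")
  }
  list(mu = mu, logvar = logvar)
}

#' Draw latent samples by reparameterisation
#'
#' `z = mu + exp(logvar / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param posterior List with `mu`, `logvar` (as from [encode()]).
#' @return Matrix of the same shape as `mu`.
#' @export
sample_latent <- function(posterior) {
  mu <- posterior$mu
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(posterior$logvar / 2) * eps
}

#' Decode latent vectors to image patches
#'
#' @param model A `manifold_model`.
#' @param z Latent matrix (`N x latent_dim`) or a single vector.
#' @return `(H, W, N)` array of patches in `[0, 1]` (a matrix when `N = 1`).
#' @export
decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(z) != model$latent_dim) {
    stop("z must have ", model$latent_dim, " columns")
  }
  y <- net_forward(model$decoder, z, training = FALSE)$out
  d <- dim(y)
  out <- array(y, c(d[1], d[2], d[3]))
  if (d[3] == 1L) matrix(out, d[1], d[2]) else out
}

#' Discriminator realness scores and similarity features
#'
#' @param model A `manifold_model`.
#' @param images Patches as in [encode()].
#' @return List with `realness` (vector in (0,1)) and `features`
#'   (`N x F` matrix from the feature map after the 4th conv block).
#' @export
discriminate <- function(model, images) {
  x <- as_batch(images, model$patch_size)
  fi <- attr(model$discriminator, "feature_index")
  fwd <- net_forward(model$discriminator, x, training = FALSE)
  feat <- fwd$outs[[fi]]
  d <- dim(feat)
  feat <- aperm(feat, c(3, 1, 2, 4))
  dim(feat) <- c(d[3], d[1] * d[2] * d[4])
  list(realness = as.numeric(fwd$out), features = feat)
}

#' Kullback-Leibler divergence of a diagonal-Gaussian posterior from N(0, I)
#'
#' Closed form `0.5 * sum_d (mu_d^2 + exp(logvar_d) - logvar_d - 1)`,
#' per sample.
#'
#' @param posterior List with `mu`, `logvar` matrices (rows = samples).
#' @return Non-negative numeric vector, one value per row; zero iff
#'   `mu = 0, logvar = 0`.
#' @examples
#' kl_divergence(list(mu = matrix(1), logvar = matrix(0)))  # 0.5
#' @export
kl_divergence <- function(posterior) {
  mu <- rbind(posterior$mu)
  lv <- rbind(posterior$logvar)
  as.numeric(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))
}

#' Reconstruction loss: pixel MSE plus learned similarity
#'
#' `MSE(x, x_rec) + lambda_feat * MSE(features(x), features(x_rec))`, with the
#' feature maps taken from the discriminator. Symmetric in its image
#' arguments and zero when they are identical.
#'
#' @param model A `manifold_model` (supplies the similarity features).
#' @param x,x_rec Image batches of identical shape.
#' @param lambda_feat Weight of the learned-similarity term (0 disables it).
#' @return List with `total`, `pixel`, `feature`.
#' @export
reconstruction_loss <- function(model, x, x_rec, lambda_feat = 1) {
  xa <- as_batch(x, model$patch_size)
  xr <- as_batch(x_rec, model$patch_size)
  if (!identical(dim(xa), dim(xr))) stop("x and x_rec shapes differ")
  pixel <- mean((xa - xr)^2)
  feature <- 0
  if (lambda_feat > 0) {
    fx <- discriminate(model, xa)$features
    fr <- discriminate(model, xr)$features
    feature <- mean((fx - fr)^2)
  }
  list(total = pixel + lambda_feat * feature, pixel = pixel, feature = feature)
}

#' Non-saturating GAN losses from discriminator outputs
#'
#' @param d_real Discriminator probabilities on real patches.
#' @param d_fake Discriminator probabilities on generated patches.
#' @return List with `disc` (`-mean[log D(real) + log(1 - D(fake))]`) and
#'   `gen` (`-mean[log D(fake)]`).
#' @examples
#' adversarial_losses(0.5, 0.5)  # disc = 2 log 2, gen = log 2
#' @export
adversarial_losses <- function(d_real, d_fake) {
  eps <- 1e-7
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  list(disc = -mean(log(d_real) + log(1 - d_fake)),
       gen = -mean(log(d_fake)))
}

#' Save / load a manifold model
#'
#' The parameter arrays round-trip exactly, so forward passes after reload are
#' bit-identical.
#'
#' @param model A `manifold_model`.
#' @param path File path for the checkpoint (`.rds`); a JSON sidecar
#'   `<path>.json` records the hyperparameters.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- model[c("patch_size", "latent_dim", "enc_channels", "dense_units",
                  "disc_channels", "stage_reached", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "manifold_model"))
  model
}
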