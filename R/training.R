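# Three-stage optimisation schedule for the VAE-GAN manifold:
#   stage 1 -- reconstruction warm-up with a low KL weight,
#   stage 2 -- linear KL-weight annealing to constrain the latent space,
#   stage 3 -- temporal cycle-consistency fine-tuning across trajectories.
# Each stage checkpoints on a held-out validation split and restores the best
# checkpoint on early stop.

#' Training schedule for the manifold model
#'
#' @param epochs_per_stage Epochs per training stage.
#' @param lr Adam learning rate for all three optimisers (encoder, generator,
#'   discriminator).
#' @param kl_weight_initial,kl_weight_final KL-term weights; the KL is
#'   normalised per latent dimension before weighting.
#' @param kl_anneal_epochs Length of the stage-2 linear ramp; default half of
#'   `epochs_per_stage`.
#' @param tcc_weight Weight of the cycle-consistency loss in stage 3.
#' @param lambda_feat Weight of the learned-similarity reconstruction term.
#' @param adv_weight Weight of the generator's adversarial term relative to
#'   the reconstruction terms (the discriminator's own loss is unweighted).
#' @param checkpoint_every Validation / checkpoint cadence in epochs.
#' @param early_stop_patience Checkpoints without improvement before a stage
#'   stops early.
#' @param batch_size Minibatch size in frames.
#' @param tcc_temperature Softmax temperature for the TCC loss.
#' @param tcc_window Maximum frames per trajectory used in one TCC pair.
#' @param val_fraction Fraction of training trajectories held out for early
#'   stopping (at least one trajectory).
#' @param stages Which stages to run (contiguous from 1).
#' @param seed RNG seed for batching, sampling and TCC pair choice.
#' @return A `training_schedule` object.
#' @export
training_schedule <- function(epochs_per_stage = 1000,
                              lr = 1e-4,
                              kl_weight_initial = 1e-3,
                              kl_weight_final = 1,
                              kl_anneal_epochs = NULL,
                              tcc_weight = 0.1,
                              lambda_feat = 1,
                              adv_weight = 0.01,
                              checkpoint_every = 10,
                              early_stop_patience = 20,
                              batch_size = 32,
                              tcc_temperature = 1,
                              tcc_window = 64,
                              val_fraction = 0.1,
                              stages = 1:3,
                              seed = 1L) {
  if (is.null(kl_anneal_epochs)) kl_anneal_epochs <- ceiling(epochs_per_stage / 2)
  stopifnot(epochs_per_stage >= 1, lr > 0, kl_weight_initial >= 0,
            kl_weight_final >= kl_weight_initial, kl_anneal_epochs >= 1,
            tcc_weight >= 0, lambda_feat >= 0, adv_weight >= 0,
            checkpoint_every >= 1,
            early_stop_patience >= 1, batch_size >= 1,
            tcc_temperature > 0, tcc_window >= 2,
            all(stages %in% 1:3), identical(stages, seq_along(stages)) || all(diff(stages) == 1))
  structure(list(epochs_per_stage = as.integer(epochs_per_stage), lr = lr,
                 kl_weight_initial = kl_weight_initial,
                 kl_weight_final = kl_weight_final,
                 kl_anneal_epochs = as.integer(kl_anneal_epochs),
                 tcc_weight = tcc_weight, lambda_feat = lambda_feat,
                 adv_weight = adv_weight,
                 checkpoint_every = as.integer(checkpoint_every),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 tcc_temperature = tcc_temperature,
                 tcc_window = as.integer(tcc_window),
                 val_fraction = val_fraction,
                 stages = as.integer(stages),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' KL annealing weight at a given epoch
#'
#' Stage 1 uses the initial weight, stage 3 the final weight; stage 2 ramps
#' linearly from initial to final over `kl_anneal_epochs`, then stays
#' constant. Monotone non-decreasing in `epoch`.
#'
#' @param epoch Zero-based epoch within stage 2.
#' @param schedule A [training_schedule()].
#' @param stage Training stage (1, 2 or 3).
#' @return KL weight.
#' @examples
#' s <- training_schedule(epochs_per_stage = 200, kl_weight_initial = 0,
#'                        kl_weight_final = 1, kl_anneal_epochs = 100)
#' kl_annealing_weight(50, s)  # 0.5
#' @export
kl_annealing_weight <- function(epoch, schedule, stage = 2) {
  stopifnot(epoch >= 0)
  if (stage == 1) return(schedule$kl_weight_initial)
  if (stage == 3) return(schedule$kl_weight_final)
  frac <- min(epoch / schedule$kl_anneal_epochs, 1)
  schedule$kl_weight_initial +
    frac * (schedule$kl_weight_final - schedule$kl_weight_initial)
}

#' Total training loss with per-term breakdown
#'
#' Combines the loss terms of one minibatch according to the stage: pixel MSE,
#' learned-similarity feature MSE, per-dimension-normalised KL at the
#' stage/epoch-dependent weight, the generator's adversarial term, and (stage
#' 3 only) the weighted TCC loss. The breakdown sums to the total.
#'
#' @param stage Training stage (1, 2, 3).
#' @param terms List with raw values `pixel`, `feature`, `kl` (mean per-sample
#'   KL), `adv_gen`, `tcc` (may be omitted outside stage 3).
#' @param schedule A [training_schedule()].
#' @param epoch Zero-based epoch within the stage (for annealing).
#' @param latent_dim Latent dimensionality used for KL normalisation.
#' @return List with `total` and weighted `breakdown`.
#' @export
total_loss <- function(stage, terms, schedule, epoch = 0, latent_dim = 16) {
  if (!stage %in% 1:3) stop("stage must be 1, 2 or 3")
  w_kl <- kl_annealing_weight(epoch, schedule, stage)
  breakdown <- c(pixel = terms$pixel,
                 feature = schedule$lambda_feat * terms$feature,
                 kl = w_kl * terms$kl / latent_dim,
                 adv_gen = schedule$adv_weight * terms$adv_gen,
                 tcc = if (stage == 3) schedule$tcc_weight * (terms$tcc %||% 0) else 0)
  list(total = sum(breakdown), breakdown = breakdown, kl_weight = w_kl)
}

# ---- internal training machinery -------------------------------------------

# stack all frames of a trajectory list into one (H, W, N, 1) array
stack_frames <- function(trajectories) {
  mats <- lapply(trajectories, function(tr) tr$images)
  n <- vapply(mats, function(m) dim(m)[3], integer(1))
  p <- dim(mats[[1]])[1]
  out <- array(0, c(p, p, sum(n), 1))
  at <- 0
  for (m in mats) {
    k <- dim(m)[3]
    out[, , at + seq_len(k), 1] <- m
    at <- at + k
  }
  out
}

clamp_logvar <- function(lv) pmin(pmax(lv, -LOGVAR_CLAMP), LOGVAR_CLAMP)

# Precise batch-norm: recompute every BN layer's running statistics from one
# full pass over the training frames (momentum forced to 1), so that
# evaluation-mode forward passes reflect the current weights rather than a
# lagging moving average.
with_bn_momentum <- function(net, mom) {
  for (l in seq_along(net)) if (net[[l]]$type == "bn") net[[l]]$momentum <- mom
  net
}

refresh_bn <- function(model, x) {
  fi <- attr(model$discriminator, "feature_index")
  enc <- net_forward(with_bn_momentum(model$encoder, 1), x, training = TRUE)
  model$encoder <- with_bn_momentum(enc$net, 0.1)
  L <- model$latent_dim
  mu <- enc$out[, seq_len(L), drop = FALSE]
  dec <- net_forward(with_bn_momentum(model$decoder, 1), mu, training = TRUE)
  model$decoder <- with_bn_momentum(dec$net, 0.1)
  dsc <- net_forward(with_bn_momentum(model$discriminator, 1), x, training = TRUE)
  model$discriminator <- with_bn_momentum(dsc$net, 0.1)
  attr(model$discriminator, "feature_index") <- fi
  model
}

# evaluation-mode VAE terms on a frame array (no adversarial, no tcc)
eval_vae_terms <- function(model, x, lambda_feat) {
  enc <- net_forward(model$encoder, x, training = FALSE)
  L <- model$latent_dim
  mu <- enc$out[, seq_len(L), drop = FALSE]
  lv <- clamp_logvar(enc$out[, L + seq_len(L), drop = FALSE])
  xr <- net_forward(model$decoder, mu, training = FALSE)$out
  pixel <- mean((x - xr)^2)
  feature <- 0
  if (lambda_feat > 0) {
    fi <- attr(model$discriminator, "feature_index")
    fx <- net_forward(model$discriminator, x, training = FALSE, upto = fi)$out
    fr <- net_forward(model$discriminator, xr, training = FALSE, upto = fi)$out
    feature <- mean((fx - fr)^2)
  }
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))
  list(pixel = pixel, feature = feature, kl = kl)
}

#' Mean pixel reconstruction error of a model on a frame stack
#'
#' Encodes with the posterior mean and decodes; used for validation and for
#' comparing trained against untrained models.
#'
#' @param model A `manifold_model`.
#' @param images `(H, W, N)` array or `(H, W, 1, N)` batch.
#' @return Mean squared pixel error.
#' @export
evaluate_reconstruction <- function(model, images) {
  x <- as_batch(images, model$patch_size)
  post <- encode(model, x)
  xr <- net_forward(model$decoder, post$mu, training = FALSE)$out
  mean((x - xr)^2)
}

model_params <- function(model) {
  list(e = lapply(model$encoder, function(l) c(l["params"], l["state"])),
       d = lapply(model$decoder, function(l) c(l["params"], l["state"])),
       c = lapply(model$discriminator, function(l) c(l["params"], l["state"])))
}

restore_params <- function(model, snap) {
  put <- function(net, saved) {
    for (i in seq_along(net)) {
      if (!is.null(saved[[i]]$params)) net[[i]]$params <- saved[[i]]$params
      if (!is.null(saved[[i]]$state)) net[[i]]$state <- saved[[i]]$state
    }
    net
  }
  fi <- attr(model$discriminator, "feature_index")
  model$encoder <- put(model$encoder, snap$e)
  model$decoder <- put(model$decoder, snap$d)
  model$discriminator <- put(model$discriminator, snap$c)
  attr(model$discriminator, "feature_index") <- fi
  model
}

#' Train the manifold model with the three-stage schedule
#'
#' Runs the staged optimisation on a list of trajectories: a validation split
#' (by trajectory) is carved out for early stopping; every
#' `checkpoint_every` epochs the validation loss of the current stage is
#' evaluated, the best parameter snapshot is kept, and a stage stops early
#' after `early_stop_patience` checkpoints without improvement (the best
#' snapshot is restored). Stage 3 additionally samples one pair of distinct
#' trajectories per minibatch and descends the TCC loss through the encoder.
#'
#' @param trajectories List of `cell_trajectory` objects (>= 2 when stage 3 is
#'   enabled).
#' @param schedule A [training_schedule()].
#' @param model Optional pre-built [manifold_model()]; by default one is
#'   created to match the trajectory patch size.
#' @param latent_dim,enc_channels,dense_units,disc_channels Passed to
#'   [manifold_model()] when `model` is `NULL`.
#' @param verbose Print per-checkpoint progress.
#' @return The trained `manifold_model`, with a `training_log` tibble field
#'   (one row per epoch and loss term) and `stage_reached` set.
#' @export
train_manifold <- function(trajectories, schedule = training_schedule(),
                           model = NULL, latent_dim = 16,
                           enc_channels = c(32, 64, 128), dense_units = 256,
                           disc_channels = c(32, 64, 128, 256),
                           verbose = FALSE) {
  stopifnot(length(trajectories) >= 1)
  if (3 %in% schedule$stages && length(trajectories) < 2) {
    stop("stage 3 (TCC) requires at least 2 trajectories")
  }
  patch <- dim(trajectories[[1]]$images)[1]
  set.seed(schedule$seed)
  if (is.null(model)) {
    model <- manifold_model(patch_size = patch, latent_dim = latent_dim,
                            enc_channels = enc_channels,
                            dense_units = dense_units,
                            disc_channels = disc_channels,
                            seed = schedule$seed)
  }
  if (model$patch_size != patch) stop("model patch size does not match data")
  L <- model$latent_dim

  # trajectory-level validation split
  n_cells <- length(trajectories)
  n_val <- max(1L, min(n_cells - 1L, round(schedule$val_fraction * n_cells)))
  val_idx <- sample(n_cells, n_val)
  train_trajs <- trajectories[setdiff(seq_len(n_cells), val_idx)]
  val_trajs <- trajectories[val_idx]
  x_train <- stack_frames(train_trajs)
  x_val <- stack_frames(val_trajs)
  n_train <- dim(x_train)[4]

  opt_e <- adam_init(model$encoder)
  opt_d <- adam_init(model$decoder)
  opt_c <- adam_init(model$discriminator)
  t_e <- t_d <- t_c <- 0L
  fi <- attr(model$discriminator, "feature_index")
  bs <- min(schedule$batch_size, n_train)
  log_rows <- list()
  global_epoch <- 0L

  val_loss_fn <- function(stage, epoch) {
    terms <- eval_vae_terms(model, x_val, schedule$lambda_feat)
    terms$adv_gen <- 0
    terms$tcc <- 0
    if (stage == 3 && length(val_trajs) >= 2) {
      u <- encode(model, val_trajs[[1]]$images)$mu
      v <- encode(model, val_trajs[[2]]$images)$mu
      w <- min(schedule$tcc_window, nrow(u), nrow(v))
      terms$tcc <- tcc_loss(u[seq_len(w), , drop = FALSE],
                            v[seq_len(w), , drop = FALSE],
                            schedule$tcc_temperature)
    }
    total_loss(stage, terms, schedule, epoch, L)$total
  }

  model <- refresh_bn(model, x_train)
  baseline_val_pixel <- eval_vae_terms(model, x_val, 0)$pixel
  stage_end_val_pixel <- c()

  for (stage in schedule$stages) {
    best <- list(loss = Inf, snap = model_params(model))
    strikes <- 0L
    for (epoch in seq_len(schedule$epochs_per_stage) - 1L) {
      w_kl <- kl_annealing_weight(epoch, schedule, stage)
      ord <- sample(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      ep_terms <- c(pixel = 0, feature = 0, kl = 0, adv_gen = 0,
                    adv_disc = 0, tcc = 0)
      for (b in batches) {
        x <- x_train[, , b, , drop = FALSE]
        nb <- length(b)

        # ---- forward: encoder -> sample -> decoder (training mode) ----
        enc <- net_forward(model$encoder, x, training = TRUE)
        model$encoder <- enc$net
        mu <- enc$out[, seq_len(L), drop = FALSE]
        lv_raw <- enc$out[, L + seq_len(L), drop = FALSE]
        lv <- clamp_logvar(lv_raw)
        lv_mask <- (lv_raw > -LOGVAR_CLAMP & lv_raw < LOGVAR_CLAMP) * 1
        eps_z <- matrix(stats::rnorm(length(mu)), nb, L)
        z <- mu + exp(lv / 2) * eps_z
        dec <- net_forward(model$decoder, z, training = TRUE)
        model$decoder <- dec$net
        xr <- dec$out

        # ---- discriminator forwards (shared by D and G losses) ----
        dr <- net_forward(model$discriminator, x, training = TRUE)
        model$discriminator <- dr$net
        df <- net_forward(model$discriminator, xr, training = TRUE)
        model$discriminator <- df$net
        o_r <- pmin(pmax(as.numeric(dr$out), 1e-7), 1 - 1e-7)
        o_f <- pmin(pmax(as.numeric(df$out), 1e-7), 1 - 1e-7)
        adv <- adversarial_losses(o_r, o_f)
        g_r <- net_backward(model$discriminator, dr,
                            dy = matrix(-1 / o_r / nb))$grads
        g_f <- net_backward(model$discriminator, df,
                            dy = matrix(1 / (1 - o_f) / nb))$grads

        # ---- generator + encoder losses ----
        pixel <- mean((xr - x)^2)
        d_xr <- 2 * (xr - x) / length(x)
        gen_loss <- -mean(log(o_f))
        feature <- 0
        inj <- NULL
        if (schedule$lambda_feat > 0) {
          f_x <- dr$outs[[fi]]   # real-image features: similarity target
          f_r <- df$outs[[fi]]
          feature <- mean((f_x - f_r)^2)
          inj <- schedule$lambda_feat * 2 * (f_r - f_x) / length(f_x)
        }
        dD <- net_backward(model$discriminator, df,
                           dy = matrix(-schedule$adv_weight / o_f / nb),
                           inject_at = if (!is.null(inj)) fi else NULL,
                           inject_grad = inj,
                           need_input_grad = TRUE)
        d_xr <- d_xr + dD$dx

        # discriminator steps after the generator gradients are taken
        gc_all <- grads_add(grads_add(NULL, g_r), g_f)
        t_c <- t_c + 1L
        upd <- adam_step(model$discriminator, gc_all, opt_c, schedule$lr, t_c)
        fi_keep <- attr(model$discriminator, "feature_index")
        model$discriminator <- upd$net
        attr(model$discriminator, "feature_index") <- fi_keep
        opt_c <- upd$state

        bdec <- net_backward(model$decoder, dec, dy = d_xr,
                             need_input_grad = TRUE)
        dz <- bdec$dx
        kl_row <- 0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
        kl <- mean(kl_row)
        kl_scale <- w_kl / (nb * L)
        dmu <- dz + kl_scale * mu
        dlv <- (dz * eps_z * 0.5 * exp(lv / 2) +
                  kl_scale * 0.5 * (exp(lv) - 1)) * lv_mask
        benc <- net_backward(model$encoder, enc, dy = cbind(dmu, dlv))

        tcc_val <- 0
        ge_all <- grads_add(NULL, benc$grads)
        if (stage == 3) {
          pick <- sample(length(train_trajs), 2)
          seqs <- lapply(pick, function(i) {
            img <- train_trajs[[i]]$images
            Tn <- dim(img)[3]
            w <- min(schedule$tcc_window, Tn)
            s0 <- if (Tn > w) sample(Tn - w, 1) else 0L
            as_batch(img[, , s0 + seq_len(w)], patch)
          })
          fa <- net_forward(model$encoder, seqs[[1]], training = TRUE)
          model$encoder <- fa$net
          fb <- net_forward(model$encoder, seqs[[2]], training = TRUE)
          model$encoder <- fb$net
          ua <- fa$out[, seq_len(L), drop = FALSE]
          ub <- fb$out[, seq_len(L), drop = FALSE]
          tc <- tcc_loss(ua, ub, schedule$tcc_temperature, grad = TRUE)
          tcc_val <- tc$loss
          zpad <- function(d) cbind(d, matrix(0, nrow(d), L))
          ga <- net_backward(model$encoder, fa,
                             dy = schedule$tcc_weight * zpad(tc$dU))$grads
          gb <- net_backward(model$encoder, fb,
                             dy = schedule$tcc_weight * zpad(tc$dV))$grads
          ge_all <- grads_add(grads_add(ge_all, ga), gb)
        }

        t_e <- t_e + 1L
        upd <- adam_step(model$encoder, ge_all, opt_e, schedule$lr, t_e)
        model$encoder <- upd$net; opt_e <- upd$state
        t_d <- t_d + 1L
        upd <- adam_step(model$decoder, bdec$grads, opt_d, schedule$lr, t_d)
        model$decoder <- upd$net; opt_d <- upd$state

        batch_terms <- c(pixel = pixel, feature = feature, kl = kl,
                         adv_gen = gen_loss, adv_disc = adv$disc,
                         tcc = tcc_val)
        if (any(!is.finite(batch_terms))) {
          stop("non-finite loss encountered in stage ", stage, ", epoch ",
               epoch, ": ", paste(names(batch_terms), signif(batch_terms, 3),
                                  sep = "=", collapse = ", "))
        }
        ep_terms <- ep_terms + batch_terms * nb
      }
      ep_terms <- ep_terms / n_train
      tl <- total_loss(stage, as.list(ep_terms), schedule, epoch, L)
      global_epoch <- global_epoch + 1L
      val <- NA_real_
      if ((epoch + 1L) %% schedule$checkpoint_every == 0L ||
          epoch + 1L == schedule$epochs_per_stage) {
        model <- refresh_bn(model, x_train)
        val <- val_loss_fn(stage, epoch)
        if (val < best$loss) {
          best <- list(loss = val, snap = model_params(model))
          strikes <- 0L
        } else {
          strikes <- strikes + 1L
        }
        if (verbose) {
          message(sprintf("stage %d epoch %d: train %.5f val %.5f", stage,
                          epoch + 1L, tl$total, val))
        }
      }
      log_rows[[global_epoch]] <- tibble::tibble(
        stage = stage, epoch = epoch + 1L, global_epoch = global_epoch,
        pixel = ep_terms[["pixel"]], feature = ep_terms[["feature"]],
        kl = ep_terms[["kl"]], kl_weight = tl$kl_weight,
        adv_gen = ep_terms[["adv_gen"]], adv_disc = ep_terms[["adv_disc"]],
        tcc = ep_terms[["tcc"]], total = tl$total, val_loss = val)
      if (strikes >= schedule$early_stop_patience) break
    }
    model <- restore_params(model, best$snap)
    model$stage_reached <- stage
    stage_end_val_pixel[as.character(stage)] <- eval_vae_terms(model, x_val, 0)$pixel
  }
  model$baseline_val_pixel <- baseline_val_pixel
  model$stage_end_val_pixel <- stage_end_val_pixel
  model$training_log <- dplyr::bind_rows(log_rows)
  model$schedule <- schedule
  model$val_cells <- vapply(val_trajs, function(tr) tr$cell_id, character(1))
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a manifold model
#'
#' @param x A trained `manifold_model`.
#' @param ... Unused.
#' @return Long tibble with one row per epoch and loss term.
#' @method tidy manifold_model
#' @export
tidy.manifold_model <- function(x, ...) {
  if (is.null(x$training_log)) {
    stop("model has no training log (untrained?)")
  }
  tidyr::pivot_longer(x$training_log,
                      cols = c("pixel", "feature", "kl", "adv_gen",
                               "adv_disc", "tcc", "total", "val_loss"),
                      names_to = "term", values_to = "value")
}

#' One-row summary of a trained manifold model
#'
#' @param x A trained `manifold_model`.
#' @param ... Unused.
#' @return Tibble with patch size, latent dim, stage reached, epochs run and
#'   final losses.
#' @method glance manifold_model
#' @export
glance.manifold_model <- function(x, ...) {
  lg <- x$training_log
  tibble::tibble(patch_size = x$patch_size, latent_dim = x$latent_dim,
                 stage_reached = x$stage_reached,
                 epochs_run = if (is.null(lg)) 0L else nrow(lg),
                 final_total = if (is.null(lg)) NA_real_ else utils::tail(lg$total, 1),
                 final_val = if (is.null(lg)) NA_real_ else
                   utils::tail(stats::na.omit(lg$val_loss), 1))
}
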