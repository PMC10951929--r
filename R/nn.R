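# Compact neural-network engine used by the VAE-GAN.
#
# Activations live as (H, W, N, C) arrays between convolutional layers -- a
# layout in which every reshape needed around the BLAS matrix multiplies is a
# free dim<- change -- and as (N, F) matrices between dense layers.
# Convolutions are one precomputed index gather (im2col) followed by
# crossprod(); transposed convolutions are the exact adjoint of the paired
# convolution (dilate + flipped-kernel convolution), so one pair of
# primitives serves the forward and backward passes of both.

# ---- geometry helpers -------------------------------------------------------

# Gather index for a padded (Hp, Wp, N, C) input: a (KC, P*N) index matrix
# where KC = k*k*C taps (tap fastest, then channel) and columns run over
# output positions (column-major over Ho x Wo), then samples.
.geom_cache <- new.env(parent = emptyenv())
im2col_idx <- function(Hp, Wp, N, C, k, s) {
  key <- paste(Hp, Wp, N, C, k, s, sep = "_")
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  pos_r <- rep(seq.int(0L, by = s, length.out = Ho), times = Wo)
  pos_c <- rep(seq.int(0L, by = s, length.out = Wo), each = Ho)
  kr <- rep(seq_len(k), times = k)
  kc <- rep(seq_len(k), each = k)
  base <- outer(kr, pos_r, "+") + Hp * outer(kc - 1L, pos_c, "+")  # (k2, P)
  A <- base[rep(seq_len(k * k), C), , drop = FALSE] +
    rep((seq_len(C) - 1L) * (Hp * Wp * N), each = k * k)
  idx <- outer(as.vector(A), (seq_len(N) - 1L) * (Hp * Wp), "+")
  # keep as a plain vector: matrix subscripts with ncol == 4 would be taken
  # as coordinate rows by R
  out <- list(idx = as.vector(idx), dim = c(k * k * C, Ho * Wo * N),
              Ho = Ho, Wo = Wo)
  .geom_cache[[key]] <- out
  out
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

dilate_hw <- function(x, s) {
  if (s == 1) return(x)
  d <- dim(x)
  out <- array(0, c((d[1] - 1) * s + 1, (d[2] - 1) * s + 1, d[3], d[4]))
  out[seq.int(1L, by = s, length.out = d[1]),
      seq.int(1L, by = s, length.out = d[2]), , ] <- x
  out
}

# x: (H, W, N, Cin); Wmat: (k*k*Cin, Cout). Returns y (Ho, Wo, N, Cout) and
# the (KC, P*N) gathered matrix for weight gradients.
conv_fwd <- function(x, Wmat, b = NULL, k, s, p, keep_cols = TRUE) {
  d <- dim(x)
  xp <- pad_hw(x, p)
  g <- im2col_idx(dim(xp)[1], dim(xp)[2], d[3], d[4], k, s)
  Xcol <- xp[g$idx]
  dim(Xcol) <- g$dim
  Y <- crossprod(Xcol, Wmat)                     # (P*N, Cout)
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(g$Ho, g$Wo, d[3], ncol(Wmat))
  list(y = Y, Xcol = if (keep_cols) Xcol else NULL, Ho = g$Ho, Wo = g$Wo)
}

# flip kernel spatially and swap in/out channels: (k*k*Cin, Cout) ->
# (k*k*Cout, Cin)
flip_kernel <- function(Wmat, k, cin, cout) {
  Wa <- array(Wmat, c(k, k, cin, cout))
  Wf <- aperm(Wa[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  matrix(Wf, k * k * cout, cin)
}

# Gradient of conv_fwd w.r.t. its input; identically the forward pass of the
# paired transposed convolution. dy: (Ho, Wo, N, Cout) -> (H, W, N, Cin).
conv_input_grad <- function(dy, Wmat, k, s, p, cin) {
  cout <- ncol(Wmat)
  Wf <- flip_kernel(Wmat, k, cin, cout)
  dyd <- dilate_hw(dy, s)
  full <- conv_fwd(dyd, Wf, NULL, k, 1L, k - 1L, keep_cols = FALSE)$y
  d <- dim(full)
  if (p > 0) full <- full[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
  full
}

# ---- layers -----------------------------------------------------------------

init_w <- function(fan_in, n, gain = 2) {
  stats::rnorm(n, 0, sqrt(gain / fan_in))
}

layer_conv <- function(cin, cout, k = 4L, s = 2L, p = 1L) {
  list(type = "conv", cin = cin, cout = cout, k = k, s = s, p = p,
       params = list(W = matrix(init_w(k * k * cin, k * k * cin * cout),
                                k * k * cin, cout),
                     b = numeric(cout)))
}

# Transposed conv mapping cin (small grid) -> cout (doubled grid). Weights are
# stored in the orientation of the paired conv (big -> small).
layer_convt <- function(cin, cout, k = 4L, s = 2L, p = 1L) {
  list(type = "convt", cin = cin, cout = cout, k = k, s = s, p = p,
       params = list(W = matrix(init_w(k * k * cin, k * k * cout * cin),
                                k * k * cout, cin),
                     b = numeric(cout)))
}

layer_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)),
       state = list(mean = numeric(C), var = rep(1, C)))
}

layer_dense <- function(fin, fout) {
  list(type = "dense", fin = fin, fout = fout,
       params = list(W = matrix(init_w(fin, fin * fout, gain = 1), fin, fout),
                     b = numeric(fout)))
}

layer_flatten <- function() list(type = "flatten", params = list())
layer_unflatten <- function(H, W, C) {
  list(type = "unflatten", H = H, W = W, C = C, params = list())
}
layer_act <- function(kind, alpha = 0.2) {
  list(type = "act", kind = kind, alpha = alpha, params = list())
}

# per-channel matrix view of an (H, W, N, C) array: (H*W*N, C), free reshape
channels_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      out <- conv_fwd(x, layer$params$W, layer$params$b,
                      layer$k, layer$s, layer$p)
      list(y = out$y, cache = list(Xcol = out$Xcol, din = dim(x)), layer = layer)
    },
    convt = {
      y <- conv_input_grad(x, layer$params$W, layer$k, layer$s, layer$p,
                           cin = layer$cout)
      d <- dim(y)
      y <- y + rep(layer$params$b, each = prod(d[1:3]))
      dim(y) <- d
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      conv_mode <- length(d) == 4
      xm <- if (conv_mode) channels_mat(x) else x
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * mu
        layer$state$var <- (1 - layer$momentum) * layer$state$var + layer$momentum * v
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
      }
      istd <- 1 / sqrt(v + layer$eps)
      m <- nrow(xm)
      xhat <- (xm - rep(mu, each = m)) * rep(istd, each = m)
      ym <- xhat * rep(layer$params$gamma, each = m) +
        rep(layer$params$beta, each = m)
      if (conv_mode) dim(ym) <- d
      list(y = ym, cache = list(xhat = xhat, istd = istd, din = d,
                                conv_mode = conv_mode, training = training),
           layer = layer)
    },
    dense = {
      y <- x %*% layer$params$W
      y <- y + rep(layer$params$b, each = nrow(y))
      list(y = y, cache = list(x = x), layer = layer)
    },
    flatten = {
      # (H, W, N, C) -> (N, H*W*C), feature order (h, w, c) per sample
      d <- dim(x)
      y <- aperm(x, c(3, 1, 2, 4))
      dim(y) <- c(d[3], d[1] * d[2] * d[4])
      list(y = y, cache = list(din = d), layer = layer)
    },
    unflatten = {
      N <- nrow(x)
      y <- array(x, c(N, layer$H, layer$W, layer$C))
      y <- aperm(y, c(2, 3, 1, 4))
      list(y = y, cache = list(), layer = layer)
    },
    act = {
      y <- switch(layer$kind,
        relu = pmax(x, 0),
        lrelu = pmax(x, 0) + layer$alpha * pmin(x, 0),
        sigmoid = 1 / (1 + exp(-x)),
        tanh = tanh(x))
      list(y = y, cache = list(x = x, y = y), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      dym <- dy
      dim(dym) <- c(prod(dim(dy)[1:3]), dim(dy)[4])
      dW <- cache$Xcol %*% dym
      db <- colSums(dym)
      dx <- if (need_dx) {
        conv_input_grad(dy, layer$params$W, layer$k, layer$s, layer$p,
                        cin = layer$cin)
      } else NULL
      list(dx = dx, grads = list(W = dW, b = db))
    },
    convt = {
      db <- colSums(channels_mat(dy))
      bwd <- conv_fwd(dy, layer$params$W, NULL, layer$k, layer$s, layer$p)
      dW <- bwd$Xcol %*% channels_mat(cache$x)
      list(dx = if (need_dx) bwd$y else NULL,
           grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$din
      dym <- if (cache$conv_mode) channels_mat(dy) else dy
      m <- nrow(dym)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      if (!need_dx) return(list(dx = NULL, grads = list(gamma = dgamma, beta = dbeta)))
      dxhat <- dym * rep(layer$params$gamma, each = m)
      if (cache$training) {
        t1 <- dxhat - rep(colMeans(dxhat), each = m)
        t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
        dxm <- (t1 - t2) * rep(cache$istd, each = m)
      } else {
        dxm <- dxhat * rep(cache$istd, each = m)
      }
      if (cache$conv_mode) dim(dxm) <- d
      list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
    },
    dense = {
      list(dx = if (need_dx) dy %*% t(layer$params$W) else NULL,
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    flatten = {
      d <- cache$din
      dx <- array(dy, c(d[3], d[1], d[2], d[4]))
      list(dx = aperm(dx, c(2, 3, 1, 4)), grads = list())
    },
    unflatten = {
      d <- dim(dy)
      dx <- aperm(dy, c(3, 1, 2, 4))
      dim(dx) <- c(d[3], d[1] * d[2] * d[4])
      list(dx = dx, grads = list())
    },
    act = {
      dx <- switch(layer$kind,
        relu = dy * (cache$x > 0),
        lrelu = dy * ((cache$x > 0) + layer$alpha * (cache$x <= 0)),
        sigmoid = dy * cache$y * (1 - cache$y),
        tanh = dy * (1 - cache$y^2))
      list(dx = dx, grads = list())
    })
}

# Forward through a layer list. Returns output, per-layer caches, and the
# (possibly state-updated, for batch norm) layer list.
net_forward <- function(net, x, training = FALSE, upto = NULL) {
  caches <- vector("list", length(net))
  outs <- vector("list", length(net))
  last <- if (is.null(upto)) length(net) else upto
  for (l in seq_len(last)) {
    step <- layer_forward(net[[l]], x, training)
    caches[[l]] <- step$cache
    net[[l]] <- step$layer
    x <- step$y
    outs[[l]] <- x
  }
  list(out = x, caches = caches, net = net, outs = outs)
}

# Backward through a layer list. dy may be NULL (zero) if inject_grad supplies
# a mid-network gradient (gradient w.r.t. the output of layer inject_at).
# Unless need_input_grad, the first layer's (expensive, unused) input
# gradient is skipped.
net_backward <- function(net, fwd, dy = NULL, inject_at = NULL,
                         inject_grad = NULL, upto = NULL,
                         need_input_grad = FALSE) {
  last <- if (is.null(upto)) length(net) else upto
  grads <- vector("list", length(net))
  d <- dy
  for (l in rev(seq_len(last))) {
    if (!is.null(inject_at) && l == inject_at) {
      d <- if (is.null(d)) inject_grad else d + inject_grad
    }
    if (is.null(d)) stop("no gradient flowing at layer ", l)
    step <- layer_backward(net[[l]], fwd$caches[[l]], d,
                           need_dx = l > 1 || need_input_grad)
    grads[[l]] <- step$grads
    d <- step$dx
  }
  list(dx = d, grads = grads)
}

# ---- optimiser --------------------------------------------------------------

adam_init <- function(net) {
  lapply(net, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net)) {
    for (nm in names(net[[l]]$params)) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      st <- state[[l]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      net[[l]]$params[[nm]] <- net[[l]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# Sum two grads structures (for accumulating losses into one optimiser step).
grads_add <- function(a, b, w = 1) {
  if (is.null(a)) {
    return(lapply(b, function(lg) lapply(lg, function(g) w * g)))
  }
  for (l in seq_along(b)) {
    for (nm in names(b[[l]])) {
      a[[l]][[nm]] <- a[[l]][[nm]] + w * b[[l]][[nm]]
    }
  }
  a
}
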