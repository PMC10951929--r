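# Latent embedding of trajectories and 2-D projection of the manifold.

#' Embed a trajectory as its per-frame latent means
#'
#' Uses the posterior mean (not a sample), so the embedding is deterministic.
#'
#' @param model A trained `manifold_model`.
#' @param trajectory A `cell_trajectory`.
#' @return Tibble with `cell_id`, `frame`, `time_min` and latent columns
#'   `z1..zL`.
#' @export
embed_trajectory <- function(model, trajectory) {
  post <- encode(model, trajectory$images)
  z <- post$mu
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  dplyr::bind_cols(tibble::tibble(cell_id = trajectory$cell_id,
                                  frame = seq_len(nrow(z)),
                                  time_min = trajectory$time_min),
                   tibble::as_tibble(z))
}

#' Embed a list of trajectories
#'
#' @param model A trained `manifold_model`.
#' @param trajectories List of `cell_trajectory` objects.
#' @return Row-bound tibble of [embed_trajectory()] results.
#' @export
embed_dataset <- function(model, trajectories) {
  purrr::map_dfr(trajectories, function(tr) embed_trajectory(model, tr))
}

latent_matrix <- function(latents) {
  if (is.matrix(latents)) return(latents)
  zc <- grep("^z[0-9]+$", names(latents), value = TRUE)
  if (length(zc) == 0) stop("no latent columns z1..zL found")
  as.matrix(latents[zc])
}

#' Fit a 2-D projector on pooled training latents
#'
#' Fits a linear 2-D view of the latent space, deterministic and with exact
#' out-of-sample projection for held-out latents. The projector is fit on
#' training latents only and reused unchanged on evaluation data.
#'
#' Without an anchor the axes are the leading principal components. With an
#' `anchor` -- a per-frame, annotation-free covariate such as the temporal
#' distance to the nearest division event -- axis 1 is the latent direction
#' whose projection best tracks the anchor ranks (least squares on ranks),
#' signed so the anchor increases along it (divisions/mitoses at the
#' minimum), and the remaining axes are the leading principal components of
#' the residual variance. This pins the cycle progression to axis 1 the way
#' nonlinear neighbourhood embeddings tend to do by construction, which a
#' plain principal-component rotation cannot guarantee.
#'
#' @param latents Latent tibble (columns `z1..zL`) or numeric matrix with at
#'   least 10 rows.
#' @param n_components Output dimensionality (default 2).
#' @param anchor Optional numeric vector (one value per latent row, `NA`
#'   allowed) anchoring axis 1, e.g. frames to the nearest division.
#' @param seed Accepted for interface stability; the fit is deterministic and
#'   does not consume randomness.
#' @return A `latent_projector` object.
#' @export
fit_projection <- function(latents, n_components = 2, anchor = NULL, seed = 1L) {
  Z <- latent_matrix(latents)
  if (nrow(Z) < 10) stop("need at least 10 latent vectors to fit a projection")
  set.seed(seed)
  ctr <- colMeans(Z)
  Zc <- Z - rep(ctr, each = nrow(Z))
  if (is.null(anchor)) {
    basis <- stats::prcomp(Zc, center = FALSE, rank. = n_components)$rotation
    anchored <- FALSE
  } else {
    if (length(anchor) != nrow(Z)) stop("anchor length must match latents")
    ok <- is.finite(anchor)
    if (sum(ok) < 10) stop("too few finite anchor values")
    w <- stats::lm.fit(cbind(1, Zc[ok, , drop = FALSE]),
                       rank(anchor[ok]))$coefficients[-1]
    w <- w / sqrt(sum(w^2))
    resid <- Zc - outer(as.numeric(Zc %*% w), w)
    rest <- stats::prcomp(resid, center = FALSE,
                          rank. = n_components - 1)$rotation
    basis <- cbind(w, rest)
    anchored <- TRUE
  }
  colnames(basis) <- paste0("axis", seq_len(n_components))
  structure(list(center = ctr, basis = basis, anchored = anchored,
                 n_components = as.integer(n_components),
                 latent_dim = ncol(Z), orientation_sign = 1,
                 rotation = diag(n_components)),
            class = "latent_projector")
}

#' Project latents to 2-D manifold coordinates
#'
#' @param projector A `latent_projector` from [fit_projection()].
#' @param latents Latent tibble or matrix (same latent dimension as the fit).
#' @return For a tibble input, the tibble with `proj1`, `proj2` columns
#'   appended (with the projector's orientation applied); for a matrix, the
#'   coordinate matrix.
#' @export
project_latents <- function(projector, latents) {
  Z <- latent_matrix(latents)
  if (ncol(Z) != projector$latent_dim) stop("latent dimension mismatch")
  P <- (Z - rep(projector$center, each = nrow(Z))) %*% projector$basis
  P <- P %*% projector$rotation
  P[, 1] <- projector$orientation_sign * P[, 1]
  colnames(P) <- paste0("proj", seq_len(ncol(P)))
  if (is.matrix(latents)) return(P)
  dplyr::bind_cols(latents, tibble::as_tibble(P))
}

#' Normalise the orientation of the projection plane
#'
#' The orientation of a fitted projection is arbitrary per fit. This aligns
#' the plane so that mitotic (reference) frames sit at the minimum end of the
#' first axis, giving downstream trajectory analytics a consistent
#' orientation. `method = "rotate"` (default) applies the rigid in-plane
#' rotation taking the direction from the cloud centre to the reference
#' centroid onto the negative first axis; `method = "flip"` only chooses the
#' sign of axis 1. Both are idempotent.
#'
#' @param projector A `latent_projector`.
#' @param projected Tibble of projected frames (from [project_latents()],
#'   typically the training frames).
#' @param reference Logical vector or integer row indices flagging M-like
#'   frames (e.g. division frames or GMM M calls).
#' @param method `"rotate"` or `"flip"`.
#' @return The projector with its orientation set; re-project to apply.
#' @export
orient_projection <- function(projector, projected, reference,
                              method = c("rotate", "flip")) {
  method <- match.arg(method)
  if (is.logical(reference)) reference <- which(reference)
  if (length(reference) == 0) {
    warning("no reference frames; leaving orientation unchanged")
    return(projector)
  }
  P <- if (is.matrix(projected)) projected else
    as.matrix(projected[paste0("proj", seq_len(projector$n_components))])
  if (projector$n_components < 2) method <- "flip"
  if (method == "flip") {
    if (mean(P[reference, 1]) > mean(P[-reference, 1])) {
      projector$orientation_sign <- -projector$orientation_sign
    }
    return(projector)
  }
  u <- colMeans(P[reference, 1:2, drop = FALSE]) - colMeans(P[, 1:2])
  nu <- sqrt(sum(u^2))
  if (nu < .Machine$double.eps) {
    warning("reference centroid coincides with the cloud centre; leaving ",
            "orientation unchanged")
    return(projector)
  }
  u <- u / nu
  # proper rotation sending u -> (-1, 0): reference frames end up at the
  # minimum pole of axis 1 (undo any prior sign flip first)
  P0 <- P
  P0[, 1] <- projector$orientation_sign * P0[, 1]
  u0 <- colMeans(P0[reference, 1:2, drop = FALSE]) - colMeans(P0[, 1:2])
  u0 <- u0 / sqrt(sum(u0^2))
  R <- diag(projector$n_components)
  R[1:2, 1:2] <- cbind(c(-u0[1], -u0[2]), c(u0[2], -u0[1]))
  projector$rotation <- projector$rotation %*% R
  projector$orientation_sign <- 1
  projector
}

#' @export
print.latent_projector <- function(x, ...) {
  cat("Latent projector: ", x$latent_dim, "-d -> ", x$n_components,
      "-d (principal components), orientation sign ", x$orientation_sign,
      "\n", sep = "")
  invisible(x)
}
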