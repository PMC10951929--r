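# Temporal cycle-consistency (TCC) alignment loss.
#
# A reference embedding u_i is softly matched into a second sequence V via a
# softmax over negative squared distances; the resulting soft nearest
# neighbour must "cycle back" and classify the original frame index i among
# the frames of U. The training loss is the mean cross-entropy of that
# cycle-back classification, which is differentiable in both sequences.

sq_dists <- function(u, M) {
  # squared Euclidean distances from vector u to each row of M
  colSums((t(M) - u)^2)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Soft nearest neighbour of an embedding in a second sequence
#'
#' `alpha_j = softmax_j(-||u_i - v_j||^2 / temperature)`;
#' `v_tilde = sum_j alpha_j v_j`.
#'
#' @param u_i Numeric latent vector.
#' @param V Matrix whose rows are the frames of the second sequence.
#' @param temperature Softmax temperature on the squared distances.
#' @return List with `alpha` (weights, sum 1) and `v_tilde`.
#' @export
soft_nearest_neighbor <- function(u_i, V, temperature = 1) {
  V <- rbind(V)
  if (nrow(V) < 1) stop("V must contain at least one frame")
  if (ncol(V) != length(u_i)) stop("dimension mismatch between u_i and V")
  alpha <- softmax(-sq_dists(u_i, V) / temperature)
  list(alpha = alpha, v_tilde = as.numeric(crossprod(alpha, V)))
}

#' Cycle-back classification distribution over the frames of U
#'
#' `beta_k = softmax_k(-||v_tilde - u_k||^2 / temperature)`.
#'
#' @param v_tilde Soft nearest neighbour vector.
#' @param U Matrix whose rows are the frames of the original sequence.
#' @inheritParams soft_nearest_neighbor
#' @return Probability vector over the rows of U.
#' @export
cycle_back_distribution <- function(v_tilde, U, temperature = 1) {
  U <- rbind(U)
  if (nrow(U) < 1) stop("U must contain at least one frame")
  if (ncol(U) != length(v_tilde)) stop("dimension mismatch between v_tilde and U")
  softmax(-sq_dists(v_tilde, U) / temperature)
}

#' Temporal cycle-consistency loss between two embedding sequences
#'
#' Mean over reference frames i of the cross-entropy `-log beta_i`, where
#' `beta` is the cycle-back distribution of the soft nearest neighbour of
#' `u_i` in `V`. Low loss means frames cycle back to themselves, i.e. the two
#' sequences are temporally aligned in embedding space.
#'
#' @param U,V Matrices (frames x latent_dim), each with at least 2 rows.
#' @param temperature Softmax temperature.
#' @param grad If `TRUE`, also return analytic gradients `dU`, `dV`.
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `(loss, dU, dV)`.
#' @export
tcc_loss <- function(U, V, temperature = 1, grad = FALSE) {
  U <- rbind(U); V <- rbind(V)
  if (nrow(U) < 2 || nrow(V) < 2) stop("sequences must have length >= 2")
  if (ncol(U) != ncol(V)) stop("latent dimensions differ")
  Tu <- nrow(U)
  loss <- 0
  dU <- matrix(0, nrow(U), ncol(U))
  dV <- matrix(0, nrow(V), ncol(V))
  for (i in seq_len(Tu)) {
    u_i <- U[i, ]
    snn <- soft_nearest_neighbor(u_i, V, temperature)
    alpha <- snn$alpha
    vt <- snn$v_tilde
    beta <- cycle_back_distribution(vt, U, temperature)
    loss <- loss - log(max(beta[i], 1e-300))
    if (grad) {
      # d(-log beta_i)/d t_k = beta_k - 1{k==i}; t_k = -||vt - u_k||^2 / tau
      dt <- beta
      dt[i] <- dt[i] - 1
      diffU <- sweep(U, 2, vt, "-")            # rows: u_k - vt
      dvt <- as.numeric(crossprod(dt, diffU)) * (2 / temperature)
      dU <- dU - (2 / temperature) * dt * diffU
      # vt = sum_j alpha_j v_j
      dV <- dV + alpha %o% dvt
      dalpha <- as.numeric(V %*% dvt)
      ds <- alpha * (dalpha - sum(alpha * dalpha))  # softmax backward
      diffV <- sweep(V, 2, u_i, "-")            # rows: v_j - u_i
      dU[i, ] <- dU[i, ] + (2 / temperature) * as.numeric(crossprod(ds, diffV))
      dV <- dV - (2 / temperature) * ds * diffV
    }
  }
  loss <- loss / Tu
  if (!grad) return(loss)
  list(loss = loss, dU = dU / Tu, dV = dV / Tu)
}
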