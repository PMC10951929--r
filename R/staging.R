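# Population-level cell-cycle staging: Gaussian-mixture clustering of the
# latent space, majority-vote naming of components against post hoc labels,
# merging of same-stage components, and the temporal G1-G2 constraint.

#' Fit a Gaussian mixture model on pooled latents
#'
#' Full-covariance mixture with more components than biological stages; the
#' surplus components capture sub-populations within a stage and are merged
#' after naming. Fitting is delegated to \pkg{mclust} with a conjugate prior
#' for numerical stability.
#'
#' @param latents Latent tibble (`z1..zL`) or matrix.
#' @param k Number of mixture components (default 8).
#' @param seed RNG seed (mclust initialisation is deterministic; the seed
#'   guards any subset sampling).
#' @return A `stage_gmm` object wrapping the mclust fit.
#' @importFrom mclust Mclust mclustBIC priorControl
#' @export
fit_gmm <- function(latents, k = 8, seed = 1L) {
  Z <- latent_matrix(latents)
  if (nrow(Z) <= k * ncol(Z)) {
    stop("need more than k * latent_dim = ", k * ncol(Z), " points to fit ",
         k, " full-covariance components")
  }
  set.seed(seed)
  fit <- mclust::Mclust(Z, G = k, modelNames = "VVV",
                        prior = mclust::priorControl(),
                        verbose = FALSE)
  if (is.null(fit)) stop("GMM fit failed")
  structure(list(fit = fit, k = as.integer(k), latent_dim = ncol(Z)),
            class = "stage_gmm")
}

#' Mixture responsibilities and hard component assignments
#'
#' @param gmm A `stage_gmm`.
#' @param latents Latent tibble or matrix.
#' @return List with `responsibilities` (n x k matrix, rows sum to 1) and
#'   `component` (argmax component id per frame).
#' @export
gmm_responsibilities <- function(gmm, latents) {
  Z <- latent_matrix(latents)
  pr <- stats::predict(gmm$fit, newdata = Z)
  list(responsibilities = pr$z, component = as.integer(pr$classification))
}

#' Name mixture components by majority vote of post hoc stage labels
#'
#' Labels are used only here -- after self-supervised training -- to attach
#' stage names to the discovered clusters. Each component gets its modal
#' label; ties go to the stage with more frames overall, then to the
#' canonical stage order.
#'
#' @param assignments Integer component ids (1..k) per frame.
#' @param labels Stage labels per frame (subset of [CYCLE_STAGES]).
#' @param k Number of components (default `max(assignments)`).
#' @return Character vector of length `k`: component -> stage.
#' @export
majority_stage_mapping <- function(assignments, labels, k = max(assignments)) {
  if (length(assignments) != length(labels)) {
    stop("assignments and labels must have equal length")
  }
  if (!all(labels %in% CYCLE_STAGES)) stop("unknown stage label in labels")
  global_rank <- table(factor(labels, levels = CYCLE_STAGES))
  vapply(seq_len(k), function(cmp) {
    lab <- labels[assignments == cmp]
    if (length(lab) == 0) {
      warning("component ", cmp, " is empty; mapping to the globally most ",
              "frequent stage")
      lab <- labels
    }
    counts <- table(factor(lab, levels = CYCLE_STAGES))
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) {
      # tie: more frames overall wins, then canonical order
      top <- top[order(-global_rank[top], match(top, CYCLE_STAGES))]
    }
    top[1]
  }, character(1))
}

#' Merge same-stage components into a predictive staging model
#'
#' Components that share a majority stage are merged into one predictive
#' stage; a frame's call is the stage of its argmax-responsibility component.
#'
#' @param gmm A `stage_gmm`.
#' @param mapping Component -> stage map from [majority_stage_mapping()].
#' @return A `stage_cluster_model`.
#' @export
merge_components <- function(gmm, mapping) {
  stopifnot(length(mapping) == gmm$k, all(mapping %in% CYCLE_STAGES))
  structure(list(gmm = gmm, mapping = mapping,
                 stages = CYCLE_STAGES[CYCLE_STAGES %in% unique(mapping)]),
            class = "stage_cluster_model")
}

#' @export
print.stage_cluster_model <- function(x, ...) {
  cat("Stage cluster model: ", x$gmm$k, " components -> ",
      length(x$stages), " stages (", paste(x$stages, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Classify frames into cell-cycle stages
#'
#' @param model A `stage_cluster_model`.
#' @param latents Latent tibble or matrix.
#' @return Character vector of stage calls (deterministic).
#' @export
classify_frames <- function(model, latents) {
  comp <- gmm_responsibilities(model$gmm, latents)$component
  unname(model$mapping[comp])
}

#' Confusion matrix and frame-level accuracy
#'
#' @param pred,truth Equal-length stage vectors over [CYCLE_STAGES].
#' @return List with `confusion` (true x predicted count matrix in canonical
#'   stage order) and `accuracy` (percent, `100 * trace / sum`).
#' @export
confusion_and_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (!all(pred %in% CYCLE_STAGES) || !all(truth %in% CYCLE_STAGES)) {
    stop("unknown stage label")
  }
  cm <- table(truth = factor(truth, levels = CYCLE_STAGES),
              predicted = factor(pred, levels = CYCLE_STAGES))
  cm <- unclass(cm)
  list(confusion = cm, accuracy = 100 * sum(diag(cm)) / sum(cm))
}

#' Apply the temporal G1-G2 constraint to a stage-call sequence
#'
#' G1 and G2 are morphologically similar growth stages separated by S; given
#' the inferred late-S time of a trajectory, any G1 call at or after that
#' frame is reclassified as G2 and any G2 call before it as G1. All other
#' calls are untouched, and the operation is idempotent.
#'
#' @param stages Character vector of per-frame stage calls.
#' @param lateS_frame Frame index of the inferred late-S peak (a frame equal
#'   to `lateS_frame` counts as "after").
#' @return Corrected stage-call vector.
#' @examples
#' apply_g1g2_constraint(c("G1", "G2", "lateS", "G1", "G2"), 3)
#' @export
apply_g1g2_constraint <- function(stages, lateS_frame) {
  n <- length(stages)
  if (length(lateS_frame) != 1 || lateS_frame < 1 || lateS_frame > n) {
    stop("lateS_frame out of range")
  }
  idx <- seq_len(n)
  stages[stages == "G1" & idx >= lateS_frame] <- "G2"
  stages[stages == "G2" & idx < lateS_frame] <- "G1"
  stages
}

#' Apply the G1-G2 constraint cycle by cycle
#'
#' Segments a trajectory at its detected mitosis troughs and applies
#' [apply_g1g2_constraint()] within each segment that contains an inferred
#' late-S frame; frames in segments without a late-S assignment are left
#' unchanged.
#'
#' @param stages Per-frame stage calls for one trajectory.
#' @param events A `key_events` object from [assign_key_stages()].
#' @return Corrected stage-call vector.
#' @export
constrain_stage_calls <- function(stages, events) {
  n <- length(stages)
  ev <- events$events
  m_frames <- sort(ev$frame[ev$stage %in% "M"])
  bounds <- unique(c(1L, m_frames, n + 1L))
  lateS <- ev$frame[ev$stage %in% "lateS"]
  for (s in seq_len(length(bounds) - 1)) {
    lo <- bounds[s]; hi <- bounds[s + 1] - 1L
    if (hi < lo) next
    ls <- lateS[lateS >= lo & lateS <= hi]
    if (length(ls) == 0) next
    seg <- stages[lo:hi]
    stages[lo:hi] <- apply_g1g2_constraint(seg, ls[1] - lo + 1L)
  }
  stages
}
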