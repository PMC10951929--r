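# brute-force reimplementation of the G1-G2 rule, used as an oracle
g1g2_oracle <- function(stages, lateS_frame) {
  out <- stages
  for (i in seq_along(stages)) {
    if (stages[i] == "G1" && i >= lateS_frame) out[i] <- "G2"
    if (stages[i] == "G2" && i < lateS_frame) out[i] <- "G1"
  }
  out
}

test_that("the mixture model recovers well-separated clusters", {
  set.seed(30)
  n <- 150
  Z <- rbind(matrix(rnorm(n * 4), n) + 10, matrix(rnorm(n * 4), n) - 10)
  truth <- rep(1:2, each = n)
  g <- fit_gmm(Z, k = 2, seed = 1)
  comp <- gmm_responsibilities(g, Z)$component
  expect_gt(mclust::adjustedRandIndex(comp, truth), 0.95)

  resp <- gmm_responsibilities(g, Z[sample(2 * n, 20), ])$responsibilities
  expect_equal(unname(rowSums(resp)), rep(1, 20))

  g2 <- fit_gmm(Z, k = 2, seed = 1)
  expect_equal(g$fit$parameters$mean, g2$fit$parameters$mean)
  expect_error(fit_gmm(matrix(0, 6, 4), k = 2), "points")
})

test_that("majority naming follows modal labels with declared tie rules", {
  expect_identical(
    majority_stage_mapping(rep(1, 12), c(rep("G1", 10), rep("G2", 2)), k = 1),
    "G1")

  # three components all majority-G1 map to G1 (merge comes later)
  asg <- rep(1:3, each = 10)
  lab <- rep(c("G1", "G1", "G1"), each = 10)
  lab[c(1, 11, 21)] <- "M"
  expect_identical(unname(majority_stage_mapping(asg, lab, k = 3)),
                   rep("G1", 3))

  # exact tie: the globally more frequent stage wins
  asg <- c(rep(1, 10), rep(2, 3))
  lab <- c(rep("G1", 5), rep("G2", 5), rep("G1", 3))
  expect_identical(unname(majority_stage_mapping(asg, lab, k = 2))[1], "G1")

  expect_warning(
    map <- majority_stage_mapping(rep(1, 4), rep("G2", 4), k = 2),
    "empty")
  expect_identical(unname(map[2]), "G2")
  expect_error(majority_stage_mapping(1:2, c("G1", "weird")), "unknown")
})

test_that("merging components yields a total stage classifier", {
  g <- gaussian_stage_latents(n_per = 50, dim = 8, sep = 15,
                              stages = c("G1", "earlyS", "lateS", "G2", "M"))
  gm <- fit_gmm(g$latents, k = 8, seed = 2)
  comp <- gmm_responsibilities(gm, g$latents)$component
  mapping <- majority_stage_mapping(comp, g$stage, k = 8)
  sm <- merge_components(gm, mapping)
  # 8 components collapse onto at most 5 named stages, every frame classified
  expect_lte(length(sm$stages), 5)
  calls <- classify_frames(sm, g$latents)
  expect_identical(length(calls), nrow(g$latents))
  expect_true(all(calls %in% CYCLE_STAGES))
  expect_identical(calls, classify_frames(sm, g$latents))

  # distinct-stage mapping merges to the identity
  m2 <- merge_components(gm, c("G1", "earlyS", "midS", "lateS", "G2", "M",
                               "G1", "G2"))
  expect_identical(m2$stages,
                   CYCLE_STAGES[CYCLE_STAGES %in% unique(m2$mapping)])

  # classification equals argmax responsibility composed with the mapping
  resp <- gmm_responsibilities(sm$gmm, g$latents)
  expect_identical(calls, unname(sm$mapping[resp$component]))
})

test_that("confusion matrix and accuracy follow the counting definition", {
  perfect <- confusion_and_accuracy(c("G1", "M"), c("G1", "M"))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  wrong <- confusion_and_accuracy(c("G1", "G1"), c("G2", "M"))
  expect_equal(wrong$accuracy, 0)

  two3 <- confusion_and_accuracy(c("G1", "G1", "M"), c("G1", "G2", "M"))
  expect_equal(two3$accuracy, 100 * 2 / 3)
  expect_equal(sum(two3$confusion), 3)

  expect_error(confusion_and_accuracy("G1", c("G1", "M")), "lengths")
  expect_error(confusion_and_accuracy("G0", "G1"), "unknown")
})

test_that("the G1-G2 constraint matches its brute-force oracle exhaustively", {
  expect_identical(apply_g1g2_constraint(c("G1", "G2", "lateS", "G1", "G2"), 3),
                   c("G1", "G1", "lateS", "G2", "G2"))
  expect_identical(apply_g1g2_constraint(c("midS", "M", "lateS"), 2),
                   c("midS", "M", "lateS"))

  alphabet <- c("G1", "G2", "lateS")
  for (len in 1:6) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      seqs <- as.character(grid[r, ])
      for (ls in seq_len(len)) {
        got <- apply_g1g2_constraint(seqs, ls)
        expect_identical(got, g1g2_oracle(seqs, ls))
        expect_identical(apply_g1g2_constraint(got, ls), got)  # idempotent
      }
    }
  }
  expect_error(apply_g1g2_constraint(c("G1", "G2"), 3), "range")
})

test_that("per-cycle constraint application respects segment boundaries", {
  stages <- c("G2", "M", "G1", "G2", "lateS", "G1", "M", "G2", "lateS", "G1")
  ev <- structure(list(events = tibble::tibble(
    frame = c(2L, 5L, 7L, 9L),
    type = c("trough", "peak", "trough", "peak"),
    stage = c("M", "lateS", "M", "lateS")),
    inflections = integer(0), complete = TRUE,
    cycle_duration_hours = NA_real_), class = "key_events")
  got <- constrain_stage_calls(stages, ev)
  # inside cycle [2, 6]: G2 before late-S at 5 becomes G1; G1 at/after stays G2
  expect_identical(got[3:6], c("G1", "G1", "lateS", "G2"))
  # second segment [7, 10]: G2 at 8 precedes late-S at 9 -> G1; G1 at 10 -> G2
  expect_identical(got[8:10], c("G1", "lateS", "G2"))
  # frames before the first M trough keep their calls when no late-S precedes
  expect_identical(got[1], "G2")
  expect_identical(constrain_stage_calls(got, ev), got)
})

test_that("with the true late-S time the constraint never lowers accuracy", {
  fr <- synthetic_config()$stage_fractions
  set.seed(77)
  for (rep in 1:25) {
    # one forward cycle sampled at regular phases, with G1/G2 call confusion
    n <- 40
    phase <- (seq_len(n) - 1) / n
    truth <- phase_to_stage(phase, fr)
    calls <- truth
    growth <- calls %in% c("G1", "G2")
    flip <- growth & runif(n) < 0.4
    calls[flip] <- ifelse(calls[flip] == "G1", "G2", "G1")
    lateS_mid <- which.min(abs(phase - (cumsum(fr)[["lateS"]] +
                                          cumsum(fr)[["midS"]]) / 2))
    before <- confusion_and_accuracy(calls, truth)$accuracy
    after <- confusion_and_accuracy(apply_g1g2_constraint(calls, lateS_mid),
                                    truth)$accuracy
    expect_gte(after, before)
  }
})
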