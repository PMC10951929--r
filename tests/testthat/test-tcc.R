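# Independent brute-force oracle: explicit loops over the softmax formulas.
tcc_oracle <- function(U, V, temperature = 1) {
  total <- 0
  for (i in seq_len(nrow(U))) {
    s <- numeric(nrow(V))
    for (j in seq_len(nrow(V))) s[j] <- -sum((U[i, ] - V[j, ])^2) / temperature
    a <- exp(s - max(s)); a <- a / sum(a)
    vt <- numeric(ncol(V))
    for (j in seq_len(nrow(V))) vt <- vt + a[j] * V[j, ]
    t_ <- numeric(nrow(U))
    for (k in seq_len(nrow(U))) t_[k] <- -sum((vt - U[k, ])^2) / temperature
    b <- exp(t_ - max(t_)); b <- b / sum(b)
    total <- total - log(b[i])
  }
  total / nrow(U)
}

test_that("soft nearest neighbour is a distance softmax", {
  sn <- soft_nearest_neighbor(c(1, 2), matrix(c(5, 5), 1))
  expect_equal(sn$alpha, 1)
  expect_equal(sn$v_tilde, c(5, 5))

  V <- rbind(c(0, 0), c(10, 0), c(0, 10))
  sn <- soft_nearest_neighbor(c(0, 0), V)
  expect_gt(sn$alpha[1], 0.99)

  set.seed(2)
  for (i in 1:5) {
    V <- matrix(rnorm(12), 4)
    expect_equal(sum(soft_nearest_neighbor(rnorm(3), V)$alpha), 1)
  }
  expect_error(soft_nearest_neighbor(1:3, matrix(0, 1, 2)), "dimension")
})

test_that("cycle-back distribution normalises and respects symmetry", {
  expect_equal(cycle_back_distribution(c(0, 0), matrix(c(3, 3), 1)), 1)
  U <- rbind(-1, 1)
  expect_equal(cycle_back_distribution(0, U), c(0.5, 0.5))
  set.seed(3)
  expect_equal(sum(cycle_back_distribution(rnorm(2), matrix(rnorm(10), 5))), 1)
})

test_that("tcc loss matches the brute-force oracle", {
  # identical well-separated sequences cycle back perfectly
  U <- matrix(c(0, 10), 2)
  expect_lt(tcc_loss(U, U), 1e-3)

  # frozen worked example, verified by direct softmax composition
  expect_equal(tcc_loss(matrix(c(0, 2), 2), matrix(c(1, 3), 2)),
               tcc_oracle(matrix(c(0, 2), 2), matrix(c(1, 3), 2)),
               tolerance = 1e-12)

  set.seed(10)
  for (i in 1:100) {
    Tu <- sample(2:20, 1); Tv <- sample(2:20, 1); d <- sample(1:8, 1)
    tau <- runif(1, 0.5, 2)
    U <- matrix(rnorm(Tu * d), Tu)
    V <- matrix(rnorm(Tv * d), Tv)
    expect_lt(abs(tcc_loss(U, V, tau) - tcc_oracle(U, V, tau)), 1e-6)
  }
})

test_that("tcc loss is translation invariant and decreases as sequences align", {
  set.seed(4)
  U <- matrix(rnorm(8), 4); V <- matrix(rnorm(8), 4)
  shift <- matrix(rep(c(3, -7), each = 4), 4)
  expect_equal(tcc_loss(U, V), tcc_loss(U + shift, V + shift), tolerance = 1e-9)

  # scaling identical, well-ordered sequences apart drives the loss to zero
  base <- matrix(seq(0, 3), 4)
  losses <- vapply(c(0.5, 1, 2, 4, 8), function(s) tcc_loss(s * base, s * base),
                   numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
  expect_lt(losses[length(losses)], 1e-6)
})

test_that("analytic tcc gradients match numerical differentiation and flow", {
  set.seed(6)
  U <- matrix(rnorm(10), 5); V <- matrix(rnorm(8), 4)
  g <- tcc_loss(U, V, temperature = 0.8, grad = TRUE)
  expect_gt(sum(abs(g$dU)), 0)
  expect_gt(sum(abs(g$dV)), 0)
  eps <- 1e-6
  for (idx in c(1, 4, 7)) {
    Up <- U; Up[idx] <- Up[idx] + eps
    Um <- U; Um[idx] <- Um[idx] - eps
    num <- (tcc_loss(Up, V, 0.8) - tcc_loss(Um, V, 0.8)) / (2 * eps)
    expect_lt(abs(g$dU[idx] - num), 1e-5)
    Vp <- V; Vp[idx] <- Vp[idx] + eps
    Vm <- V; Vm[idx] <- Vm[idx] - eps
    num <- (tcc_loss(U, Vp, 0.8) - tcc_loss(U, Vm, 0.8)) / (2 * eps)
    expect_lt(abs(g$dV[idx] - num), 1e-5)
  }
})
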