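test_that("spline smoothing preserves constants and can interpolate", {
  const <- rep(3.2, 20)
  sm <- smooth_bspline(const, 0.6)
  expect_equal(sm$smoothed, const)

  set.seed(1)
  y <- rnorm(15)
  expect_equal(smooth_bspline(y, 0)$smoothed, y)

  # denoising: smoothed curve closer to the clean signal than the raw one
  t <- 1:180
  clean <- sin(2 * pi * t / 60)
  set.seed(2)
  noisy <- clean + rnorm(180, sd = 0.3)
  sm <- smooth_bspline(noisy, 0.6)
  expect_lt(sqrt(mean((sm$smoothed - clean)^2)),
            sqrt(mean((noisy - clean)^2)))
  expect_error(smooth_bspline(1:5), "too short")
})

test_that("running average is centred with truncated edges", {
  expect_equal(running_average(c(4, 8, 1), 1)$smoothed, c(4, 8, 1))
  expect_equal(running_average(rep(2, 10), 7)$smoothed, rep(2, 10))
  expect_equal(running_average(c(0, 0, 10, 0, 0), 5)$smoothed[3], 2)
  expect_error(running_average(1:4, 5), "window")
})

test_that("extrema detection matches calculus on analytic signals", {
  t <- seq_len(120)
  one <- smooth_bspline(sin(2 * pi * t / 120), 0)
  ex <- find_extrema(one, 0.5)
  expect_identical(nrow(ex$peaks), 1L)
  expect_identical(nrow(ex$troughs), 1L)
  expect_equal(ex$peaks$frame, 30, tolerance = 1)
  expect_equal(ex$troughs$frame, 90, tolerance = 1)

  two <- smooth_bspline(sin(2 * pi * t / 60), 0)
  ex2 <- find_extrema(two, 0.5)
  expect_identical(nrow(ex2$peaks), 2L)
  expect_identical(nrow(ex2$troughs), 2L)

  mono <- find_extrema(smooth_bspline(seq(0, 5, length.out = 50), 0))
  expect_identical(nrow(mono$peaks), 0L)
  expect_identical(nrow(mono$troughs), 0L)

  # peaks and troughs swap exactly under negation
  set.seed(5)
  y <- cumsum(rnorm(80))
  cv <- smooth_bspline(y, 0.5)
  neg <- cv; neg$smoothed <- -neg$smoothed; neg$raw <- -neg$raw
  a <- find_extrema(cv, 0)
  b <- find_extrema(neg, 0)
  expect_identical(a$peaks$frame, b$troughs$frame)
  expect_identical(a$troughs$frame, b$peaks$frame)
  expect_equal(a$peaks$value, -b$troughs$value)
})

# piecewise curve with the canonical cycle shape: deep M troughs at 10/210,
# G1 peak at 60 (height 1), early-S trough at 100 (0.4), late-S peak at 150
# (height 2)
worked_cycle_curve <- function() {
  knots_x <- c(1, 10, 60, 100, 150, 210, 220)
  knots_y <- c(0, -2, 1, 0.4, 2, -2, 0)
  y <- approx(knots_x, knots_y, xout = 1:220)$y
  new_curve_local <- smooth_bspline(y, 0)
  new_curve_local
}

test_that("key stages are read off the curve extrema as described", {
  ev <- assign_key_stages(worked_cycle_curve())
  got <- ev$events
  expect_identical(got$stage[got$frame == 10], "M")
  expect_identical(got$stage[got$frame == 210], "M")
  expect_identical(got$stage[got$frame == 60], "G1")
  expect_identical(got$stage[got$frame == 100], "earlyS")
  expect_identical(got$stage[got$frame == 150], "lateS")
  expect_true(ev$complete)
  expect_identical(infer_lateS_time(ev), 150L)

  # sign-consistency: the assignment is defined on the oriented curve, and a
  # monotone segment yields no cycle but must not crash
  flat <- smooth_bspline(seq(0, 3, length.out = 30), 0)
  expect_warning(ev2 <- assign_key_stages(flat), "fewer than 2 troughs")
  expect_identical(nrow(ev2$events), 0L)
  expect_false(ev2$complete)
  expect_error(infer_lateS_time(ev2), "no late-S")
})

test_that("cycle duration is the time between the two most prominent troughs", {
  # frozen arithmetic examples
  y <- rep(0, 230)
  y[13] <- -5; y[214] <- -5
  cv <- running_average(y, 1)
  expect_equal(estimate_cycle_duration(cv, 5.9), (214 - 13) * 5.9 / 60)

  y2 <- rep(1, 80)
  y2[10] <- -1; y2[70] <- -1
  expect_equal(estimate_cycle_duration(running_average(y2, 1), 60), 60)

  # noiseless sawtooth of period P: exact recovery
  P <- 50
  saw <- rep(c(seq(0, 1, length.out = P - 5), seq(1, 0, length.out = 5)), 4)
  est <- estimate_cycle_duration(running_average(saw, 10), 6)
  expect_equal(est, P * 6 / 60)

  # invariance to offset and scale
  cv3 <- running_average(3 * saw + 11, 10)
  expect_equal(estimate_cycle_duration(cv3, 6), est)

  expect_warning(out <- estimate_cycle_duration(
    running_average(seq_len(40), 5), 5.9), "fewer than 2")
  expect_true(is.na(out))
})
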