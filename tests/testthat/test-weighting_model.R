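# Additive speed/elevation weighting regression.

grid_weightings <- function(fun) {
  out <- list()
  for (v in 1:5) for (e in c(-20, -10, 0, 10, 20)) {
    out[[length(out) + 1]] <- list(speed = v, elevation = e, W = fun(v, e))
  }
  out
}

test_that("build_delta_targets marginalizes differences against baseline", {
  m <- 6; k <- 2
  W0 <- rand_nonneg(m, k, 31)

  # identical weightings everywhere -> all deltas zero
  tg0 <- build_delta_targets(grid_weightings(function(v, e) W0))
  expect_true(all(vapply(tg0$speed$deltas, function(d) max(abs(d)), numeric(1)) < 1e-12))
  expect_true(all(vapply(tg0$elevation$deltas, function(d) max(abs(d)), numeric(1)) < 1e-12))

  # exactly linear speed surface
  tgl <- build_delta_targets(grid_weightings(function(v, e) W0 + 0.1 * (v - 3)))
  expect_equal(tgl$speed$levels, 1:5)
  for (i in seq_along(tgl$speed$levels)) {
    expect_equal(unname(tgl$speed$deltas[[i]][1, 1]),
                 0.1 * (tgl$speed$levels[i] - 3), tolerance = 1e-12)
  }
  expect_true(all(vapply(tgl$elevation$deltas, function(d) max(abs(d)), numeric(1)) < 1e-12))

  # additive quadratic elevation surface reproduced at grid points
  tgq <- build_delta_targets(grid_weightings(function(v, e) W0 + 0.002 * e^2))
  for (i in seq_along(tgq$elevation$levels)) {
    expect_equal(unname(tgq$elevation$deltas[[i]][2, 2]),
                 0.002 * tgq$elevation$levels[i]^2, tolerance = 1e-12)
  }

  expect_error(build_delta_targets(list(list(speed = 1, elevation = 0,
                                             W = W0))), "baseline")
})

test_that("fit_regression recovers constructed polynomial surfaces exactly", {
  m <- 4; k <- 3
  W0 <- rand_nonneg(m, k, 32) + 0.1

  tg <- build_delta_targets(grid_weightings(function(v, e) W0 + 0.05 * (v - 3)))
  mod <- fit_regression(tg, W0)
  expect_equal(unname(mod$speed_a1), matrix(0.05, m, k), tolerance = 1e-9)
  expect_true(all(mod$speed_degree == 1))
  expect_true(all(abs(mod$speed_a2) < 1e-9))

  tgq <- build_delta_targets(grid_weightings(function(v, e) W0 + 0.002 * e^2))
  modq <- fit_regression(tgq, W0)
  expect_equal(unname(modq$elev_a2), matrix(0.002, m, k), tolerance = 1e-9)
  expect_true(all(abs(modq$elev_a1) < 1e-9))

  tgz <- build_delta_targets(grid_weightings(function(v, e) W0))
  modz <- fit_regression(tgz, W0)
  expect_true(all(modz$speed_a1 == 0 & modz$speed_a2 == 0 &
                  modz$elev_a1 == 0 & modz$elev_a2 == 0))
})

test_that("predict_weightings honors exact identities and clipping", {
  m <- 5; k <- 2
  W0 <- rand_nonneg(m, k, 33) + 0.3   # strictly positive: surface stays additive
  tg <- build_delta_targets(grid_weightings(function(v, e)
    W0 + 0.05 * (v - 3) + 0.001 * e))
  mod <- fit_regression(tg, W0)

  # baseline condition returns W_BL bit-exactly
  expect_identical(predict_weightings(mod, 3, 0)$W, W0)

  # linear-only model: cond (5, 0) = W_BL + 2 * slope
  p5 <- predict_weightings(mod, 5, 0)
  expect_equal(p5$W, W0 + 2 * mod$speed_a1, tolerance = 1e-12)

  # subject override replaces the baseline wholesale
  Ws <- rand_nonneg(m, k, 34)
  expect_identical(predict_weightings(mod, 3, 0, baseline_override = Ws)$W, Ws)

  # negative predictions are clipped and counted
  tiny <- matrix(1e-4, m, k)
  modt <- fit_regression(tg, tiny)
  p1 <- predict_weightings(modt, 1, -20)
  expect_true(all(p1$W >= 0))
  expect_gt(p1$clipped, 0)

  expect_warning(predict_weightings(mod, 7, 0), "extrapolating")
})

test_that("the model is exactly additive and separable", {
  m <- 3; k <- 2
  W0 <- rand_nonneg(m, k, 35) + 0.5
  tg <- build_delta_targets(grid_weightings(function(v, e)
    W0 + 0.04 * (v - 3) + 0.03 * e / 10 + 0.0005 * e^2))
  mod <- fit_regression(tg, W0)
  for (e in c(-20, 0, 20)) {
    d <- predict_weightings(mod, 5, e)$W - predict_weightings(mod, 3, e)$W
    d0 <- predict_weightings(mod, 5, 0)$W - predict_weightings(mod, 3, 0)$W
    expect_equal(d, d0, tolerance = 1e-12)
  }
})

test_that("coefficients are recovered under noise within tolerance", {
  set.seed(36)
  m <- 6; k <- 4
  W0 <- rand_nonneg(m, k, 37) + 0.3
  a1 <- matrix(runif(m * k, 0.02, 0.08), m, k)
  b2 <- matrix(runif(m * k, 1e-4, 5e-4), m, k)
  # noisy observations of an additive degree-2 surface, sd 0.02
  wl <- grid_weightings(function(v, e)
    W0 + a1 * (v - 3) + b2 * e^2 + matrix(rnorm(m * k, 0, 0.02), m, k))
  mod <- fit_regression(build_delta_targets(wl), W0)
  # target noise: differencing doubles the variance, averaging over the 5
  # marginalized levels divides it by 5 -> sd 0.02 * sqrt(2/5)
  sd_t <- 0.02 * sqrt(2 / 5)
  se_a1 <- sd_t / sqrt(sum((-2:2)^2))         # slope over x in {-2..2}
  se_b2 <- sd_t / sqrt(2 * (400^2 + 100^2))   # quadratic term, orthogonal design
  # max over 24 coefficients: allow 4 standard errors
  expect_lt(max(abs(mod$speed_a1 - a1)), 4 * se_a1)
  expect_lt(max(abs(mod$elev_a2 - b2)), 4 * se_b2)
})
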