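# NNMF, VAF, dimensionality selection, normalization/scaling, matching.

test_that("compute_vaf matches hand-computed and brute-force values", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(compute_vaf(X, X), 1)
  expect_equal(compute_vaf(X, X * 0), 0)
  Xhat <- matrix(c(1, 3, 2, 0), 2, 2)
  expect_equal(compute_vaf(X, Xhat), 1 - 16 / 30, tolerance = 1e-12)
  expect_error(compute_vaf(X * 0, X), "all zero")

  set.seed(1)
  for (i in 1:20) {
    A <- matrix(runif(30), 5, 6); B <- matrix(runif(30), 5, 6)
    expect_equal(compute_vaf(A, B), brute_vaf(A, B), tolerance = 1e-12)
  }
})

test_that("nnmf_best_of_restarts recovers exact low-rank structure deterministically", {
  w <- c(0.2, 1, 0.5, 0.1, 0.8); h <- runif(40, 0, 1)
  X1 <- outer(w, h)
  f1 <- nnmf_best_of_restarts(X1, 1, restarts = 5, seed = 3)
  expect_gt(f1$vaf, 0.999)

  W <- rand_nonneg(10, 3, 5); H <- rand_nonneg(3, 60, 6)
  X3 <- W %*% H
  f3 <- nnmf_best_of_restarts(X3, 3, restarts = 10, seed = 4)
  expect_gt(f3$vaf, 0.99)

  # determinism: identical seed, bit-identical output
  g3 <- nnmf_best_of_restarts(X3, 3, restarts = 10, seed = 4)
  expect_identical(f3$weightings, g3$weightings)
  expect_identical(f3$factors, g3$factors)
  expect_identical(f3$vaf, g3$vaf)

  expect_error(nnmf_best_of_restarts(-X3, 2), "non-negative")
})

test_that("select_dimensionality applies the incremental VAF rule", {
  W <- rand_nonneg(8, 2, 7); H <- rand_nonneg(2, 50, 8)
  X <- W %*% H
  cs <- select_dimensionality(X, vaf_threshold = 0.85, restarts = 5, seed = 2)
  expect_lte(cs$rank, 2)
  expect_true(cs$threshold_reached)

  cs0 <- select_dimensionality(X, vaf_threshold = 0, restarts = 3, seed = 2)
  expect_equal(cs0$rank, 1)
})

test_that("normalize_and_scale preserves the reconstruction exactly", {
  # scale algebra: factor max 0.5, weighting 0.8 -> scaled weighting 0.4
  fac <- matrix(rep(0.5 * exp(-(cycle_grid() - 40)^2 / 200), 2), nrow = 1)
  cs <- mepmod:::new_motor_component_set(
    rank = 1, factors = fac, weightings = matrix(0.8, 1, 1), vaf = 1)
  out <- normalize_and_scale(cs, 2)
  expect_equal(max(out$avg_factors), 1)
  expect_equal(out$weightings[1, 1], 0.4, tolerance = 1e-15)
  # two identical cycles: average equals each cycle
  expect_equal(out$avg_factors[1, ], fac[1, 1:200] / 0.5, tolerance = 1e-15)

  # random valid set: product of scaled weightings and normalized averaged
  # factors equals product of originals and averaged factors to 1e-12
  set.seed(9)
  k <- 3; cycles <- 4
  facs <- rand_nonneg(k, 200 * cycles, 10)
  Wm <- rand_nonneg(15, k, 11)
  cs2 <- mepmod:::new_motor_component_set(rank = k, factors = facs,
                                          weightings = Wm, vaf = 0.9)
  out2 <- normalize_and_scale(cs2, cycles)
  avg_orig <- t(vapply(seq_len(k), function(j)
    rowMeans(matrix(facs[j, ], nrow = 200)), numeric(200)))
  expect_lt(max(abs(out2$weightings %*% out2$avg_factors - Wm %*% avg_orig)),
            1e-12)
})

test_that("match_components_by_peak orders and matches components", {
  gauss <- function(mu) exp(-(cycle_grid() - mu)^2 / (2 * 36))
  avg <- rbind(gauss(91), gauss(5), gauss(38), gauss(72))
  cs <- mepmod:::new_motor_component_set(
    rank = 4, factors = matrix(0, 4, 200), weightings = rand_nonneg(15, 4, 1),
    vaf = 0.9, avg_factors = avg)
  out <- match_components_by_peak(cs)
  expect_equal(out$component_order, c(2, 3, 4, 1))
  peaks <- apply(out$avg_factors, 1, which.max)
  expect_true(all(diff(peaks) > 0))

  # reference = self: identity permutation
  self <- match_components_by_peak(out, reference = out)
  expect_equal(self$component_order, 1:4)

  # shuffled copy of a reference: permutation recovers the original order
  perm <- c(3, 1, 4, 2)
  shuf <- out
  shuf$avg_factors <- out$avg_factors[perm, ]
  shuf$weightings <- out$weightings[, perm]
  shuf$factors <- out$factors[perm, ]
  rec <- match_components_by_peak(shuf, reference = out)
  expect_equal(rec$avg_factors, out$avg_factors)
  expect_equal(rec$weightings, out$weightings)
})

test_that("VAF is monotone in k and residual identity holds", {
  W <- rand_nonneg(8, 4, 20); H <- rand_nonneg(4, 80, 21)
  X <- W %*% H
  vafs <- suppressWarnings(vapply(1:4, function(k)
    nnmf_best_of_restarts(X, k, restarts = 5, seed = 5)$vaf, numeric(1)))
  expect_true(all(diff(vafs) > -1e-9))

  cs <- suppressWarnings(nnmf_best_of_restarts(X, 3, restarts = 5, seed = 5))
  resid <- sum((X - cs$weightings %*% cs$factors)^2)
  expect_equal(resid, (1 - cs$vaf) * sum(X^2), tolerance = 1e-9)
})

test_that("generator components are recovered with high circular correlation", {
  # low-noise world (SNR >= 10): each recovered normalized factor matches
  # one distinct ground-truth primitive
  cfg <- mini_cfg(noise_sd = 0.01, noise_cv = 0.05, jitter_sd = 0.01)
  cell <- generate_condition_cycles(cfg, 1, 3, 0)
  X <- do.call(cbind, lapply(cell$cycles, `[[`, "values"))
  cs <- nnmf_best_of_restarts(X, 4, restarts = 5, seed = 13)
  cs <- normalize_and_scale(cs, length(cell$cycles))
  cs <- match_components_by_peak(cs)
  used <- integer(0)
  for (j in 1:4) {
    cors <- vapply(1:4, function(g)
      mepmod:::max_circ_cor(evaluate_xp(cfg$primitives, g), cs$avg_factors[j, ]),
      numeric(1))
    best <- which.max(cors)
    expect_gt(cors[best], 0.9)
    used <- c(used, best)
  }
  expect_equal(sort(used), 1:4)
})
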