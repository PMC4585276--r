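# Motor-component extraction: NNMF with restarts, VAF-based dimensionality
# selection, factor averaging/normalization, and component matching.

#' Variance accounted for
#'
#' `VAF = 1 - SSE/TSS` with SSE the sum of squared reconstruction errors and
#' TSS the *uncentered* total sum of squares `sum(X^2)` (the convention of
#' the synergy literature; it makes `VAF(X, 0) = 0` hold). Can be negative
#' for reconstructions worse than the zero matrix.
#'
#' @param X observed matrix.
#' @param Xhat reconstruction, same shape.
#' @return VAF as a fraction (1 = perfect).
#' @export
compute_vaf <- function(X, Xhat) {
  stopifnot(identical(dim(as.matrix(X)), dim(as.matrix(Xhat))))
  tss <- sum(X^2)
  if (tss == 0) stop("compute_vaf: X is all zero, VAF undefined")
  1 - sum((X - Xhat)^2) / tss
}

new_motor_component_set <- function(rank, factors, weightings, vaf,
                                    muscle_labels = rownames(weightings),
                                    avg_factors = NULL, component_order = NULL,
                                    converged = NA, iterations = NA_integer_,
                                    threshold_reached = NA,
                                    degenerate = integer(0)) {
  structure(list(rank = rank, factors = factors, weightings = weightings,
                 vaf = vaf, muscle_labels = muscle_labels,
                 avg_factors = avg_factors, component_order = component_order,
                 converged = converged, iterations = iterations,
                 threshold_reached = threshold_reached,
                 degenerate = degenerate),
            class = "motor_component_set")
}

#' @export
print.motor_component_set <- function(x, ...) {
  cat(sprintf("<motor_component_set> rank %d, %d muscles, VAF %.4f\n",
              x$rank, nrow(x$weightings), x$vaf))
  invisible(x)
}

#' Non-negative matrix factorization, best of random restarts
#'
#' Factorizes a non-negative muscles x samples matrix as `W %*% H` using
#' Lee-Seung multiplicative updates (squared Frobenius objective), started
#' from `restarts` random non-negative initializations (`Uniform(0.1, 1)`).
#' The restart with the highest VAF wins. Deterministic given `seed`: each
#' restart draws its initialization under `substream_seed(seed, k, restart)`.
#'
#' @param X non-negative muscles x samples matrix.
#' @param k factorization rank (number of motor components).
#' @param restarts number of random restarts (default 50).
#' @param seed integer seed.
#' @param max_iter iteration cap per restart (default 2000).
#' @param tol convergence tolerance: stop when the decrease of the Frobenius
#'   residual norm over a 10-iteration block, relative to the initial
#'   residual norm, falls below `tol`.
#' @return A `motor_component_set` with `factors` (k x n), `weightings`
#'   (muscles x k) and `vaf`.
#' @export
nnmf_best_of_restarts <- function(X, k, restarts = 50, seed = 1,
                                  max_iter = 2000, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("nnmf_best_of_restarts: X must be non-negative")
  m <- nrow(X); n <- ncol(X)
  stopifnot(k >= 1, k <= m)
  tss <- sum(X^2)
  if (tss == 0) stop("nnmf_best_of_restarts: X is all zero")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(substream_seed(seed, k, r))
    W0 <- matrix(runif(m * k, 0.1, 1), m, k)
    H0 <- matrix(runif(k * n, 0.1, 1), k, n)
    fit <- .nmf_mu_cpp(X, W0, H0, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  if (!best$converged) {
    warning("nnmf_best_of_restarts: best restart did not converge within ",
            max_iter, " iterations; keeping best iterate")
  }
  W <- best$W
  rownames(W) <- rownames(X)
  new_motor_component_set(rank = k, factors = best$H, weightings = W,
                          vaf = 1 - best$sse / tss,
                          muscle_labels = rownames(X),
                          converged = best$converged,
                          iterations = best$iterations)
}

#' Select factorization dimensionality by incremental VAF
#'
#' Evaluates ranks k = 1, 2, ... (each the best of `restarts` NNMF runs) and
#' returns the first whose VAF reaches the threshold. If no rank up to the
#' number of muscles reaches it, the full-rank result is returned with
#' `threshold_reached = FALSE` and a warning.
#'
#' @inheritParams nnmf_best_of_restarts
#' @param vaf_threshold minimum acceptable VAF (default 0.85).
#' @return A `motor_component_set` (with `threshold_reached` flag).
#' @export
select_dimensionality <- function(X, vaf_threshold = 0.85, restarts = 50,
                                  seed = 1, max_iter = 2000, tol = 1e-6) {
  X <- as.matrix(X)
  for (k in seq_len(nrow(X))) {
    cs <- nnmf_best_of_restarts(X, k, restarts = restarts, seed = seed,
                                max_iter = max_iter, tol = tol)
    if (cs$vaf >= vaf_threshold) {
      cs$threshold_reached <- TRUE
      return(cs)
    }
  }
  warning("select_dimensionality: VAF threshold ", vaf_threshold,
          " not reached at full rank")
  cs$threshold_reached <- FALSE
  cs
}

#' Average, normalize and rescale a factorization
#'
#' Per component: the factor (a concatenation of `cycle_count` 200-sample
#' cycles) is averaged across cycles, the average is normalized to maximum
#' 1, and the component's weighting column is multiplied by the
#' pre-normalization maximum so that the product of scaled weightings and
#' normalized averaged factors equals the product of the original weightings
#' and averaged factors exactly.
#'
#' @param cs a `motor_component_set` from [nnmf_best_of_restarts()].
#' @param cycle_count number of concatenated gait cycles in `cs$factors`.
#' @return The component set with `avg_factors` (k x 200, each row max 1)
#'   and rescaled `weightings`; degenerate (all-zero) components are listed
#'   in `$degenerate`.
#' @export
normalize_and_scale <- function(cs, cycle_count) {
  n <- ncol(cs$factors)
  if (n != 200 * cycle_count) {
    stop("normalize_and_scale: factor length ", n,
         " is not 200 * cycle_count (", cycle_count, ")")
  }
  k <- cs$rank
  avg <- matrix(0, k, 200)
  degenerate <- integer(0)
  for (j in seq_len(k)) {
    a <- rowMeans(matrix(cs$factors[j, ], nrow = 200))
    cmax <- max(a)
    if (cmax <= 0) {
      degenerate <- c(degenerate, j)
      avg[j, ] <- a
      next
    }
    avg[j, ] <- a / cmax
    cs$weightings[, j] <- cs$weightings[, j] * cmax
  }
  cs$avg_factors <- avg
  cs$degenerate <- degenerate
  cs
}

# Maximum circular cross-correlation between two 200-vectors (used for
# component matching across conditions/subjects).
max_circ_cor <- function(a, b) {
  best <- -Inf
  for (s in 0:(length(a) - 1)) {
    r <- suppressWarnings(cor(a, circshift(b, s)))
    if (is.finite(r) && r > best) best <- r
  }
  best
}

#' Order or match components
#'
#' Without a reference, components are reordered by the location of the
#' maximum of their normalized averaged factor within the gait cycle
#' (ascending). With a reference set, components are greedily assigned to
#' reference components so as to maximize summed circular cross-correlation;
#' the result is returned in reference order.
#'
#' @param cs a `motor_component_set` with `avg_factors` (see
#'   [normalize_and_scale()]).
#' @param reference optional reference: a `motor_component_set` or a k x 200
#'   matrix of averaged factors.
#' @return The component set with rows/columns permuted and the permutation
#'   stored in `component_order` (original indices in new order).
#' @export
match_components_by_peak <- function(cs, reference = NULL) {
  if (is.null(cs$avg_factors)) {
    stop("match_components_by_peak: run normalize_and_scale first")
  }
  k <- cs$rank
  if (is.null(reference)) {
    perm <- order(apply(cs$avg_factors, 1, which.max))
  } else {
    ref <- if (inherits(reference, "motor_component_set")) reference$avg_factors
           else as.matrix(reference)
    if (nrow(ref) != k) {
      # rank mismatch: fall back to peak-time order
      message("match_components_by_peak: rank mismatch with reference, ",
              "falling back to peak-time order")
      perm <- order(apply(cs$avg_factors, 1, which.max))
    } else {
      score <- matrix(0, k, k)  # score[i, j]: cs component i vs reference j
      for (i in seq_len(k)) for (j in seq_len(k)) {
        score[i, j] <- max_circ_cor(ref[j, ], cs$avg_factors[i, ])
      }
      perm <- integer(k)
      taken_i <- rep(FALSE, k); taken_j <- rep(FALSE, k)
      for (step in seq_len(k)) {
        sc <- score
        sc[taken_i, ] <- -Inf; sc[, taken_j] <- -Inf
        idx <- arrayInd(which.max(sc), dim(sc))
        perm[idx[2]] <- idx[1]
        taken_i[idx[1]] <- TRUE; taken_j[idx[2]] <- TRUE
      }
    }
  }
  cs$avg_factors <- cs$avg_factors[perm, , drop = FALSE]
  cs$weightings <- cs$weightings[, perm, drop = FALSE]
  cs$factors <- cs$factors[perm, , drop = FALSE]
  cs$component_order <- perm
  cs
}
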