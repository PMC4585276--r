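# Gaussian excitation primitives (XPs): parameterization of the
# condition- and subject-invariant non-negative factors as functions of the
# gait-cycle percentage.

#' Construct an excitation-primitive parameter set
#'
#' @param components list with one entry per motor component, each a list
#'   with `mu` (peak location, percent gait cycle in `[0, 100)`), `sigma`
#'   (width, percent gait cycle, > 0) and optionally `mu2`, `sigma2`, `amp2`
#'   for a second lobe (`amp2` in `(0, 1]`, relative to the first lobe).
#' @return Object of class `xp_params`.
#' @export
xp_params <- function(components) {
  for (cmp in components) {
    stopifnot(cmp$mu >= 0, cmp$mu < 100, cmp$sigma > 0)
    if (!is.null(cmp$mu2)) {
      stopifnot(cmp$sigma2 > 0, cmp$amp2 > 0, cmp$amp2 <= 1)
    }
  }
  structure(list(components = components), class = "xp_params")
}

#' @export
print.xp_params <- function(x, ...) {
  cat(sprintf("<xp_params> %d components\n", length(x$components)))
  for (i in seq_along(x$components)) {
    cmp <- x$components[[i]]
    if (is.null(cmp$mu2)) {
      cat(sprintf("  %d: mu = %.1f%%, sigma = %.1f%%\n", i, cmp$mu, cmp$sigma))
    } else {
      cat(sprintf("  %d: mu = %.1f%%, sigma = %.1f%% + lobe (mu = %.1f%%, sigma = %.1f%%, amp = %.2f)\n",
                  i, cmp$mu, cmp$sigma, cmp$mu2, cmp$sigma2, cmp$amp2))
    }
  }
  invisible(x)
}

#' Evaluate an excitation primitive on a time grid
#'
#' The primitive is `exp(-(t - mu)^2 / (2 sigma^2))`, plus
#' `amp2 * exp(-(t - mu2)^2 / (2 sigma2^2))` when a second lobe is present,
#' renormalized to maximum 1. Distance is plain (non-circular) in percent
#' gait cycle.
#'
#' @param params an [xp_params()] object.
#' @param component component index.
#' @param t_grid evaluation grid in percent gait cycle (default
#'   [cycle_grid()]).
#' @return Numeric vector, values in `[0, 1]` with maximum 1 on any grid
#'   containing the peak.
#' @export
evaluate_xp <- function(params, component, t_grid = cycle_grid()) {
  cmp <- params$components[[component]]
  y <- exp(-(t_grid - cmp$mu)^2 / (2 * cmp$sigma^2))
  if (!is.null(cmp$mu2)) {
    y <- y + cmp$amp2 * exp(-(t_grid - cmp$mu2)^2 / (2 * cmp$sigma2^2))
  }
  y / max(y)
}

#' Evaluate all primitives into a k x length(t_grid) matrix
#'
#' @inheritParams evaluate_xp
#' @return Matrix with one row per component.
#' @export
xp_profile_matrix <- function(params, t_grid = cycle_grid()) {
  t(vapply(seq_along(params$components),
           function(j) evaluate_xp(params, j, t_grid),
           numeric(length(t_grid))))
}

xp_objective <- function(par, factor, t_grid, lobes) {
  if (lobes == 1) {
    cmp <- list(mu = par[1], sigma = par[2])
  } else {
    cmp <- list(mu = par[1], sigma = par[2],
                mu2 = par[3], sigma2 = par[4], amp2 = par[5])
  }
  p <- xp_params(list(cmp))
  mean((evaluate_xp(p, 1, t_grid) - factor)^2)
}

#' Fit a Gaussian excitation primitive to a normalized factor
#'
#' Nonlinear least squares over `(mu, sigma)`, initialized at the factor's
#' argmax and half-width at half maximum. If the unimodal residual RMS
#' exceeds `bimodal_gate` and a second local maximum of prominence >= 0.3
#' exists, a two-lobe fit is attempted and the better fit returned.
#'
#' @param factor 200-vector, non-negative, maximum 1, on [cycle_grid()].
#' @param bimodal_gate residual-RMS threshold that opens the two-lobe path
#'   (default 0.15).
#' @param force_lobes optionally force 1 or 2 lobes (used when a group of
#'   fits must agree on the lobe count).
#' @param t_grid evaluation grid (default [cycle_grid()]).
#' @return List with `params` (single-component [xp_params()] entry), `rms`
#'   (residual RMS) and `lobes`.
#' @export
fit_xp <- function(factor, bimodal_gate = 0.15, force_lobes = NULL,
                   t_grid = cycle_grid()) {
  stopifnot(length(factor) == length(t_grid), all(factor >= 0))
  imax <- which.max(factor)
  mu0 <- t_grid[imax]
  # half-width at half maximum around the main peak
  half <- factor[imax] / 2
  li <- imax; while (li > 1 && factor[li] > half) li <- li - 1
  ri <- imax; while (ri < length(factor) && factor[ri] > half) ri <- ri + 1
  hwhm <- (t_grid[ri] - t_grid[li]) / 2
  s0 <- min(max(hwhm / sqrt(2 * log(2)), 1), 50)

  fit1 <- optim(c(mu0, s0), xp_objective, factor = factor, t_grid = t_grid,
                lobes = 1, method = "L-BFGS-B",
                lower = c(0, 1), upper = c(100 - 1e-9, 50))
  rms1 <- sqrt(fit1$value)
  best <- list(params = list(mu = fit1$par[1], sigma = fit1$par[2]),
               rms = rms1, lobes = 1L,
               converged = fit1$convergence == 0)

  want2 <- if (!is.null(force_lobes)) force_lobes == 2
           else rms1 > bimodal_gate
  if (want2) {
    # peaks are sought circularly: a lobe at the very end of the cycle (late
    # swing) has negligible linear prominence but full circular prominence
    n <- length(factor)
    p3 <- find_peaks(rep(factor, 3), min_prominence = 0.3)
    peaks <- sort(unique((p3[p3 > n & p3 <= 2 * n]) - n))
    peaks <- peaks[pmin(abs(peaks - imax), n - abs(peaks - imax)) > 5]
    forced <- !is.null(force_lobes) && force_lobes == 2
    if (length(peaks) > 0 || forced) {
      mu2_0 <- if (length(peaks) > 0) {
        t_grid[peaks[which.max(factor[peaks])]]
      } else {
        (mu0 + 25) %% 100  # forced two-lobe with no visible second peak
      }
      amp2_0 <- if (length(peaks) > 0) max(factor[peaks]) else 0.5
      fit2 <- optim(c(mu0, s0, mu2_0, min(s0, 10), min(max(amp2_0, 0.05), 1)),
                    xp_objective, factor = factor, t_grid = t_grid,
                    lobes = 2, method = "L-BFGS-B",
                    lower = c(0, 1, 0, 1, 0.05),
                    upper = c(100 - 1e-9, 50, 100 - 1e-9, 50, 1))
      rms2 <- sqrt(fit2$value)
      if (forced || rms2 < rms1) {
        # keep the taller lobe first
        p <- fit2$par
        best <- list(params = list(mu = p[1], sigma = p[2],
                                   mu2 = p[3], sigma2 = p[4], amp2 = p[5]),
                     rms = rms2, lobes = 2L,
                     converged = fit2$convergence == 0)
      }
    }
  }
  if (!is.null(force_lobes) && force_lobes == 1) {
    best <- list(params = list(mu = fit1$par[1], sigma = fit1$par[2]),
                 rms = rms1, lobes = 1L, converged = fit1$convergence == 0)
  }
  best
}

#' Build generic excitation primitives from a collection of fits
#'
#' Per component, the generic parameters are the across-fit means of the
#' lobe parameters; peak locations use the circular mean on the `[0, 100)`
#' cycle. When fits disagree on the lobe count for a component, the majority
#' wins and minority cases are refit with the forced lobe count (requires
#' `factors`); without `factors` the minority fits are dropped from the
#' average.
#'
#' @param fits list over cases; each element is a list of per-component fit
#'   results as returned by [fit_xp()] (matched component order).
#' @param factors optional list over cases of k x 200 matrices of the
#'   underlying normalized factors, enabling the minority refit.
#' @return An [xp_params()] object with one entry per component.
#' @export
build_generic_xp <- function(fits, factors = NULL) {
  stopifnot(length(fits) >= 1)
  k <- length(fits[[1]])
  components <- vector("list", k)
  for (j in seq_len(k)) {
    comp_fits <- lapply(fits, `[[`, j)
    lobes <- vapply(comp_fits, `[[`, integer(1), "lobes")
    major <- if (mean(lobes == 2) > 0.5) 2L else 1L
    minority <- which(lobes != major)
    if (length(minority) > 0) {
      if (!is.null(factors)) {
        for (i in minority) {
          comp_fits[[i]] <- fit_xp(factors[[i]][j, ], force_lobes = major)
        }
      } else {
        comp_fits <- comp_fits[setdiff(seq_along(comp_fits), minority)]
      }
    }
    mus <- vapply(comp_fits, function(f) f$params$mu, numeric(1))
    sigmas <- vapply(comp_fits, function(f) f$params$sigma, numeric(1))
    entry <- list(mu = circular_mean(mus, 100), sigma = mean(sigmas))
    if (major == 2L) {
      entry$mu2 <- circular_mean(
        vapply(comp_fits, function(f) f$params$mu2, numeric(1)), 100)
      entry$sigma2 <- mean(vapply(comp_fits, function(f) f$params$sigma2, numeric(1)))
      entry$amp2 <- mean(vapply(comp_fits, function(f) f$params$amp2, numeric(1)))
    }
    components[[j]] <- entry
  }
  xp_params(components)
}
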