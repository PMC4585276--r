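# Additive speed/elevation regression of muscle weightings, anchored at the
# baseline condition (3 km/h, 0 % elevation):
#   W(v, theta) = delta_v(v) + delta_theta(theta) + W_BL
# with per-(muscle, component), per-axis polynomials through the origin of
# degree 1 or 2 (chosen by adjusted R^2).

BASELINE_SPEED <- 3
BASELINE_ELEVATION <- 0

#' Build regression targets from condition-wise weightings
#'
#' For each speed `v`, the speed-delta target is the mean over elevations of
#' `W(v, theta) - W(v_BL, theta)`; for each elevation `theta`, the
#' elevation-delta target is the mean over speeds of
#' `W(v, theta) - W(v, 0)`. Missing cells are skipped (the mean runs over
#' the cells present on both sides of the difference).
#'
#' @param weightings list of entries `list(speed=, elevation=, W=)` with `W`
#'   a muscles x k matrix, components matched across conditions.
#' @return List with `speed` (levels + list of delta matrices) and
#'   `elevation` (likewise).
#' @export
build_delta_targets <- function(weightings) {
  speeds <- sort(unique(vapply(weightings, `[[`, numeric(1), "speed")))
  elevs <- sort(unique(vapply(weightings, `[[`, numeric(1), "elevation")))
  get_W <- function(v, e) {
    for (w in weightings) {
      if (w$speed == v && w$elevation == e) return(w$W)
    }
    NULL
  }
  if (is.null(get_W(BASELINE_SPEED, BASELINE_ELEVATION))) {
    stop("build_delta_targets: baseline condition (3 km/h, 0%) missing")
  }
  speed_deltas <- lapply(speeds, function(v) {
    acc <- NULL; cnt <- 0
    for (e in elevs) {
      Wv <- get_W(v, e); Wb <- get_W(BASELINE_SPEED, e)
      if (!is.null(Wv) && !is.null(Wb)) {
        d <- Wv - Wb
        acc <- if (is.null(acc)) d else acc + d
        cnt <- cnt + 1
      }
    }
    if (cnt == 0) NULL else acc / cnt
  })
  elev_deltas <- lapply(elevs, function(e) {
    acc <- NULL; cnt <- 0
    for (v in speeds) {
      We <- get_W(v, e); Wb <- get_W(v, BASELINE_ELEVATION)
      if (!is.null(We) && !is.null(Wb)) {
        d <- We - Wb
        acc <- if (is.null(acc)) d else acc + d
        cnt <- cnt + 1
      }
    }
    if (cnt == 0) NULL else acc / cnt
  })
  keep_s <- !vapply(speed_deltas, is.null, logical(1))
  keep_e <- !vapply(elev_deltas, is.null, logical(1))
  list(speed = list(levels = speeds[keep_s], deltas = speed_deltas[keep_s]),
       elevation = list(levels = elevs[keep_e], deltas = elev_deltas[keep_e]))
}

# Average delta-target tables across subjects (elementwise; levels must
# match).
average_delta_targets <- function(target_list) {
  out <- target_list[[1]]
  for (axis in c("speed", "elevation")) {
    for (tg in target_list[-1]) {
      stopifnot(identical(tg[[axis]]$levels, out[[axis]]$levels))
      out[[axis]]$deltas <- mapply(`+`, out[[axis]]$deltas, tg[[axis]]$deltas,
                                   SIMPLIFY = FALSE)
    }
    out[[axis]]$deltas <- lapply(out[[axis]]$deltas,
                                 function(d) d / length(target_list))
  }
  out
}

# Least-squares polynomial through the origin for every (muscle, component)
# at once. Y: levels x (m*k) matrix of targets, x: centered predictor.
# Degree 1 vs 2 chosen per column by adjusted R^2 (no-intercept form).
fit_axis_poly <- function(x, Y, degree_max = 2) {
  n <- length(x)
  if (length(unique(x[x != 0])) < 1) stop("fit_axis_poly: no off-baseline levels")
  force_deg1 <- length(unique(x[x != 0])) < 2 || degree_max == 1
  X1 <- cbind(x)
  c1 <- qr.solve(X1, Y)                    # 1 x p
  rss1 <- colSums((Y - X1 %*% c1)^2)
  tss <- colSums(Y^2)
  if (!force_deg1) {
    X2 <- cbind(x, x^2)
    c2 <- qr.solve(X2, Y)
    rss2 <- colSums((Y - X2 %*% c2)^2)
    adj <- function(rss, p) {
      ifelse(tss == 0, ifelse(rss <= 1e-24, 1, -Inf),
             1 - (rss / pmax(n - p, 1)) / (tss / n))
    }
    # strict margin so an exactly-linear target never flips to degree 2 on
    # rounding noise
    use2 <- adj(rss2, 2) - adj(rss1, 1) > 1e-10
  } else {
    use2 <- rep(FALSE, ncol(Y))
  }
  a1 <- ifelse(use2, if (force_deg1) NA else c2[1, ], c1[1, ])
  a2 <- ifelse(use2, if (force_deg1) NA else c2[2, ], 0)
  zero <- tss == 0
  a1[zero] <- 0; a2[zero] <- 0
  list(a1 = a1, a2 = a2, degree = ifelse(use2, 2L, 1L))
}

#' Fit the additive weighting regression
#'
#' @param targets delta targets from [build_delta_targets()] (possibly
#'   averaged across subjects with the internal averaging helper).
#' @param baseline muscles x k non-negative baseline weighting matrix
#'   (`W_BL` at 3 km/h, 0 %).
#' @param degree_max maximum polynomial degree (default 2).
#' @return Object of class `weighting_model` with per-(muscle, component)
#'   coefficient matrices `speed_a1`, `speed_a2`, `elev_a1`, `elev_a2`,
#'   degree flags, and the baseline.
#' @export
fit_regression <- function(targets, baseline, degree_max = 2) {
  baseline <- as.matrix(baseline)
  m <- nrow(baseline); k <- ncol(baseline)
  stopifnot(all(baseline >= 0))
  flat <- function(axis, center) {
    x <- targets[[axis]]$levels - center
    Y <- do.call(rbind, lapply(targets[[axis]]$deltas, as.vector))  # levels x (m*k)
    fit_axis_poly(x, Y, degree_max)
  }
  fs <- flat("speed", BASELINE_SPEED)
  fe <- flat("elevation", BASELINE_ELEVATION)
  shape <- function(v) matrix(v, m, k, dimnames = dimnames(baseline))
  structure(list(
    baseline = baseline,
    baseline_condition = c(speed = BASELINE_SPEED, elevation = BASELINE_ELEVATION),
    speed_a1 = shape(fs$a1), speed_a2 = shape(fs$a2),
    speed_degree = shape(fs$degree),
    elev_a1 = shape(fe$a1), elev_a2 = shape(fe$a2),
    elev_degree = shape(fe$degree),
    muscle_labels = rownames(baseline),
    training_levels = list(speed = targets$speed$levels,
                           elevation = targets$elevation$levels)),
    class = "weighting_model")
}

#' @export
print.weighting_model <- function(x, ...) {
  cat(sprintf("<weighting_model> %d muscles x %d components; trained speeds {%s}, elevations {%s}\n",
              nrow(x$baseline), ncol(x$baseline),
              paste(x$training_levels$speed, collapse = ", "),
              paste(x$training_levels$elevation, collapse = ", ")))
  invisible(x)
}

#' Predict muscle weightings for a locomotion condition
#'
#' Evaluates `W = delta_v(v) + delta_theta(theta) + W_BL`, with the model
#' baseline replaced wholesale by `baseline_override` when given
#' (subject-specific mode). Negative predictions are clipped to zero and
#' counted.
#'
#' @param model a `weighting_model`.
#' @param speed speed in km/h; a warning is issued outside `[1, 5]`.
#' @param elevation elevation in percent; warning outside `[-20, 20]`.
#' @param baseline_override optional muscles x k subject baseline.
#' @return List with `W` (muscles x k), `clipped` (number of entries clipped
#'   to 0).
#' @export
predict_weightings <- function(model, speed, elevation,
                               baseline_override = NULL) {
  if (speed < 1 || speed > 5 || elevation < -20 || elevation > 20) {
    warning(sprintf("condition (%g km/h, %g%%) outside trained hull [1,5] x [-20,20]; extrapolating",
                    speed, elevation))
  }
  bl <- if (is.null(baseline_override)) model$baseline
        else as.matrix(baseline_override)
  stopifnot(identical(dim(bl), dim(model$baseline)))
  dv <- speed - model$baseline_condition[["speed"]]
  de <- elevation - model$baseline_condition[["elevation"]]
  W <- model$speed_a1 * dv + model$speed_a2 * dv^2 +
       model$elev_a1 * de + model$elev_a2 * de^2 + bl
  clipped <- sum(W < 0)
  W <- pmax(W, 0)
  list(W = W, clipped = clipped)
}
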