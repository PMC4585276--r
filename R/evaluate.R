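# Similarity metrics: shift-compensated cross-correlation, RMSE, per-
# component weighting similarity, and median/IQR summaries.

#' Shift-compensated cross-correlation of two cycle-normalized waveforms
#'
#' Finds the circular shift of `b` (over all 200 lags, i.e. +/- half a cycle)
#' that maximizes the Pearson correlation with `a`, and returns that
#' correlation together with the shift expressed in percent of the gait
#' cycle. Positive shift means `b` lags `a`. Ties are broken toward the
#' smallest absolute shift.
#'
#' @param a,b numeric vectors of equal length (non-constant).
#' @return List with `r` (correlation at the optimal shift) and
#'   `shift_percent` in `[-50, 50)`.
#' @export
xcorr_with_shift <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("xcorr_with_shift: constant input, correlation undefined")
  }
  shifts <- seq(-floor(n / 2), floor(n / 2) - 1)
  best_r <- -Inf; best_s <- 0L
  for (s in shifts) {
    r <- cor(a, circshift(b, s))
    if (r > best_r + 1e-15 ||
        (abs(r - best_r) <= 1e-15 && abs(s) < abs(best_s))) {
      best_r <- r; best_s <- s
    }
  }
  list(r = best_r, shift_percent = best_s / n * 100)
}

#' Root mean square error
#'
#' @param a,b numeric vectors (or matrices) of equal length.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) == 0) stop("rmse: empty input")
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Per-component similarity of two weighting sets
#'
#' Treats the weightings of one motor component (across muscles) as a
#' vector: returns the Pearson correlation and RMSE per component.
#'
#' @param west,wexp muscles x k matrices, matched component order.
#' @return Data frame with columns `component`, `r`, `rmse`; `r` is `NA`
#'   (flagged) for components with a constant vector on either side.
#' @export
weighting_similarity <- function(west, wexp) {
  west <- as.matrix(west); wexp <- as.matrix(wexp)
  stopifnot(identical(dim(west), dim(wexp)))
  k <- ncol(west)
  data.frame(
    component = seq_len(k),
    r = vapply(seq_len(k), function(j) {
      if (sd(west[, j]) == 0 || sd(wexp[, j]) == 0) NA_real_
      else cor(west[, j], wexp[, j])
    }, numeric(1)),
    rmse = vapply(seq_len(k), function(j) rmse(west[, j], wexp[, j]),
                  numeric(1)))
}

#' Median, interquartile range and histogram of a metric collection
#'
#' Quantiles use linear interpolation (type 7).
#'
#' @param values numeric vector (length >= 1; `NA`s dropped).
#' @param breaks histogram bin count or break vector (default 20 bins).
#' @return List with `median`, `iqr`, `q1`, `q3`, `n`, and `histogram`
#'   (list of `breaks` and `counts`).
#' @export
summarize_metric <- function(values, breaks = 20) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  list(median = q[2], iqr = q[3] - q[1], q1 = q[1], q3 = q[3],
       n = length(values),
       histogram = list(breaks = h$breaks, counts = h$counts))
}
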