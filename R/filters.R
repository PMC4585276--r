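# Butterworth design + zero-phase filtering.
#
# No filter-design package ships with the supported environment, so the
# design is done from first principles: analytic Butterworth prototype poles,
# s-domain low-pass/high-pass/band-pass transformation with bilinear
# pre-warping, then the bilinear transform to the z-domain. The result is a
# plain (b, a) transfer function; at the orders used here (<= 8) the
# polynomial form is numerically unproblematic.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth filter
#'
#' @param n prototype order (a band-pass of prototype order `n` has digital
#'   order `2n`, matching the common \code{butter(n, c(lo, hi))} convention).
#' @param fs sampling rate in Hz.
#' @param low,high cutoff frequencies in Hz; give `high` only for
#'   `type = "low"` is invalid -- see `type`.
#' @param type one of `"low"`, `"high"`, `"band"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, fs, low = NULL, high = NULL,
                          type = c("low", "high", "band")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fs > 0)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles

  if (type == "low") {
    W <- warp(low)
    poles <- proto * W
    zeros <- complex(0)
    gain <- W^n
  } else if (type == "high") {
    W <- warp(low)
    poles <- W / proto
    zeros <- rep(complex(real = 0), n)
    gain <- 1
  } else {
    W1 <- warp(low); W2 <- warp(high)
    stopifnot(W2 > W1)
    W0 <- sqrt(W1 * W2); BW <- W2 - W1
    pb <- proto * BW / 2
    poles <- c(pb + sqrt(pb^2 - W0^2), pb - sqrt(pb^2 - W0^2))
    zeros <- rep(complex(real = 0), n)
    gain <- BW^n
  }

  # bilinear transform s -> 2fs (z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # zeros at z = -1 complete the numerator to the denominator's degree
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(gain_d * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Causal IIR filtering (direct form I) built on stats::filter, zero initial
# conditions. C-speed; the per-sample loop never touches R.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering with reflection padding
#'
#' Applies the filter forward and backward (squaring the magnitude response,
#' cancelling the phase). Before filtering, the signal is extended at both
#' ends by odd reflection over `pad_s` seconds to suppress edge transients;
#' the padding is trimmed from the result.
#'
#' @param b,a transfer-function coefficients from [butter_design()].
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param pad_s padding duration in seconds (default 1; truncated to the
#'   signal length when the signal is shorter).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x, fs, pad_s = 1) {
  n <- length(x)
  pad <- min(round(pad_s * fs), n - 1)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[(pad + 1):2]
    tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(head_ref, x, tail_ref)
  } else {
    xe <- x
  }
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}
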