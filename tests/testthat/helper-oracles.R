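# Independent oracles, coded against the check targets from first
# principles. These deliberately avoid the package's own code paths.

# --- Butterworth biquad-cascade oracle ------------------------------------
# Independent design: analytic prototype poles, band transformation, poles
# paired into conjugate biquads, each biquad bilinear-transformed
# separately, cascade gain normalized analytically (exact unit gain at the
# warped center / at DC). Filtering is a plain direct-form-II loop.

oracle_butter_sos <- function(n, fs, low, high = NULL,
                              type = c("low", "band")) {
  type <- match.arg(type)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  theta <- pi * (2 * seq_len(n) + n - 1) / (2 * n)
  proto <- complex(modulus = 1, argument = theta)
  if (type == "low") {
    W <- warp(low)
    poles <- proto * W
    zero_pair <- c(-1, -1)       # both digital zeros at z = -1 per section
  } else {
    W1 <- warp(low); W2 <- warp(high)
    W0 <- sqrt(W1 * W2); BW <- W2 - W1
    pb <- proto * BW / 2
    poles <- c(pb + sqrt(pb^2 - W0^2), pb - sqrt(pb^2 - W0^2))
    zero_pair <- c(1, -1)        # one zero at z = 1, one at z = -1
  }
  # keep one pole of each conjugate pair (even n: all poles strictly complex)
  poles <- poles[Im(poles) > 1e-12]
  stopifnot(2 * length(poles) == if (type == "low") n else 2 * n)
  fs2 <- 2 * fs
  sos <- lapply(poles, function(p) {
    zp <- (fs2 + p) / (fs2 - p)
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    b <- c(1, -sum(zero_pair), prod(zero_pair))
    list(b = b, a = a)
  })
  # normalize cascade gain: unit magnitude at the digital reference
  # frequency (DC for low-pass, warped center frequency for band-pass)
  wref <- if (type == "low") 0 else 2 * atan(sqrt(warp(low) * warp(high)) / fs2)
  z <- exp(1i * wref)
  g <- prod(vapply(sos, function(s) {
    Mod(sum(s$b * z^(0:-2)) / sum(s$a * z^(0:-2)))
  }, numeric(1)))
  sos[[1]]$b <- sos[[1]]$b / g
  sos
}

oracle_biquad_filter <- function(sos, x) {
  for (s in sos) {
    b <- s$b; a <- s$a
    w1 <- 0; w2 <- 0
    y <- numeric(length(x))
    for (i in seq_along(x)) {     # direct form II, per-sample loop
      w0 <- x[i] - a[2] * w1 - a[3] * w2
      y[i] <- b[1] * w0 + b[2] * w1 + b[3] * w2
      w2 <- w1; w1 <- w0
    }
    x <- y
  }
  x
}

oracle_filtfilt <- function(sos, x, fs, pad_s = 1) {
  n <- length(x)
  pad <- min(round(pad_s * fs), n - 1)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- oracle_biquad_filter(sos, xe)
  y <- rev(oracle_biquad_filter(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

# --- scalar statistics ----------------------------------------------------

brute_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

brute_rmse <- function(a, b) sqrt(sum((a - b)^2) / length(a))

brute_vaf <- function(X, Xhat) {
  sse <- 0; tss <- 0
  for (i in seq_along(X)) {
    sse <- sse + (X[i] - Xhat[i])^2
    tss <- tss + X[i]^2
  }
  1 - sse / tss
}

# type-7 quantile by explicit linear interpolation of the order statistics
brute_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# centered moving average by explicit window loop
brute_moving_average <- function(x, width) {
  n <- length(x)
  lo <- floor((width - 1) / 2); hi <- floor(width / 2)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - lo):min(n, i + hi)
    sum(x[w]) / length(w)
  }, numeric(1))
}

# exhaustive circular shift scan (all n shifts), independent of the package
brute_best_shift <- function(a, b) {
  n <- length(a)
  best_r <- -Inf; best_s <- 0
  for (s in (-floor(n / 2)):(floor(n / 2) - 1)) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    r <- brute_pearson(a, b[idx])
    if (r > best_r + 1e-15 ||
        (abs(r - best_r) <= 1e-15 && abs(s) < abs(best_s))) {
      best_r <- r; best_s <- s
    }
  }
  list(r = best_r, shift_percent = best_s / n * 100)
}
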