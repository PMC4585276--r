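#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (subject, condition, factorization rank, restart, ...) draw their
#' own substream seed from it with a small deterministic integer hash, so
#' that changing one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the substream (coerced with
#'   `as.integer`; character arguments are hashed bytewise).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  mod <- 2147483647  # 2^31 - 1, keeps seeds valid 32-bit integers
  h <- as.numeric(master) %% mod
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "/"))
             else as.integer(part)
    for (v in codes) {
      h <- (h * 69069 + as.numeric(v) + 1) %% mod
    }
  }
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Centered moving average with edge truncation
#'
#' @param x numeric vector.
#' @param width window width in samples (>= 1); even widths are used as-is
#'   with the window `[i - floor((w-1)/2), i + floor(w/2)]`.
#' @return Vector of the same length; near the edges the window is truncated
#'   to the available samples (no padding), so no phase shift is introduced.
#' @export
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  n <- length(x)
  if (width == 1 || n == 0) return(x)
  lo <- floor((width - 1) / 2)
  hi <- floor(width / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1)
  b <- pmin(i + hi, n)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

# Local maxima with prominence and minimum-separation pruning.
# Prominence of a peak: height above the higher of the two minima separating
# it from the nearest higher ground on each side (standard definition).
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # strict local maxima; plateaus take the first sample of the plateau
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > -Inf]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    # walk left until a sample higher than x[i] (or the edge)
    left_min <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) { left_min <- min(left_min, x[j]); j <- j - 1L }
    if (j < 1L) left_min <- min(x[1:i])
    right_min <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) { right_min <- min(right_min, x[j]); j <- j + 1L }
    if (j > n) right_min <- min(x[i:n])
    x[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  # greedy pruning by height: keep the tallest, drop neighbours within min_distance
  ord <- order(x[cand], decreasing = TRUE)
  selected <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - selected) >= min_distance)) {
      selected <- c(selected, cand[i])
    }
  }
  sort(selected)
}

# Circular mean of values living on [0, period)
circular_mean <- function(x, period = 100) {
  ang <- x / period * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  out <- (m %% (2 * pi)) / (2 * pi) * period
  if (period - out < 1e-9) out <- 0  # snap wrap-around to the period origin
  out
}

# Circular (wrap-around) integer shift of a vector: positive k advances,
# i.e. circshift(x, k)[t] = x[t + k].
circshift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(k + 1):n], x[1:k])
}

# Atomic file write: write to a temp file in the same directory, then rename.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic write failed for ", path)
  }
  invisible(path)
}

# Fixed-format numeric serialization so identical numbers always produce
# identical bytes (determinism contract for all text outputs).
fmt_num <- function(x) sprintf("%.15g", x)
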