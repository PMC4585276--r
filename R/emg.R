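# EMG envelope processing: filtering, amplitude normalization, gait
# segmentation, and 200-point time normalization.

#' Construct an EMG recording
#'
#' Container for one trial of multi-muscle EMG (raw or envelope), with the
#' sampling rate and the locomotion condition it was recorded under.
#'
#' @param samples muscles x time numeric matrix (one row per muscle).
#' @param muscle_labels character vector, one label per row.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param condition numeric `c(speed, elevation)` with speed in km/h and
#'   elevation in percent.
#' @return An object of class `envelope_recording`.
#' @export
envelope_recording <- function(samples, muscle_labels, sampling_rate,
                               condition = c(speed = NA_real_, elevation = NA_real_)) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), sampling_rate > 0,
            length(muscle_labels) == nrow(samples))
  rownames(samples) <- muscle_labels
  structure(
    list(samples = samples, muscle_labels = muscle_labels,
         sampling_rate = sampling_rate,
         condition = c(speed = unname(condition[1]),
                       elevation = unname(condition[2]))),
    class = "envelope_recording")
}

#' @export
print.envelope_recording <- function(x, ...) {
  cat(sprintf("<envelope_recording> %d muscles x %d samples @ %g Hz (speed %g km/h, elevation %g%%)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              x$condition[["speed"]], x$condition[["elevation"]]))
  invisible(x)
}

#' Construct a gait-cycle matrix
#'
#' One amplitude- and time-normalized gait cycle: muscles x 200, values in
#' `[0, 1]`, columns at cycle percentages `cycle_grid()`.
#'
#' @param values muscles x 200 numeric matrix.
#' @param cycle_index ordinal position of the cycle within its trial.
#' @return Object of class `gait_cycle_matrix`.
#' @export
gait_cycle_matrix <- function(values, cycle_index = NA_integer_) {
  values <- as.matrix(values)
  if (ncol(values) != 200) stop("gait_cycle_matrix requires exactly 200 columns")
  if (anyNA(values)) stop("gait_cycle_matrix must not contain missing values")
  structure(list(values = values, cycle_index = cycle_index),
            class = "gait_cycle_matrix")
}

#' Compute linear envelopes from raw EMG
#'
#' Band-pass filters the raw signal (zero-phase Butterworth), full-wave
#' rectifies, and low-pass filters to obtain the linear envelope. Any
#' negative low-pass ringing is clipped to zero.
#'
#' @param raw an [envelope_recording()] holding raw EMG.
#' @param band band-pass edges in Hz (default 30--300).
#' @param envelope_cutoff low-pass cutoff in Hz for the envelope (default 3).
#' @param order Butterworth prototype order (default 4; the band-pass stage
#'   is therefore 8th order).
#' @return An [envelope_recording()] with non-negative envelope samples.
#' @export
compute_envelope <- function(raw, band = c(30, 300), envelope_cutoff = 3,
                             order = 4) {
  fs <- raw$sampling_rate
  if (fs < 1000) stop("compute_envelope requires sampling_rate >= 1000 Hz, got ", fs)
  if (!all(is.finite(raw$samples))) stop("compute_envelope: non-finite samples in input")
  min_len <- 10 * 2 * order  # digital band-pass order is 2 * prototype order
  if (ncol(raw$samples) <= min_len) {
    stop("compute_envelope: signal too short to filter (", ncol(raw$samples),
         " samples <= ", min_len, ")")
  }
  bp <- butter_design(order, fs, low = band[1], high = band[2], type = "band")
  lp <- butter_design(order, fs, low = envelope_cutoff, type = "low")
  env <- t(apply(raw$samples, 1, function(x) {
    y <- filtfilt_zero_phase(bp$b, bp$a, x, fs)
    y <- abs(y)
    y <- filtfilt_zero_phase(lp$b, lp$a, y, fs)
    pmax(y, 0)
  }))
  out <- raw
  out$samples <- env
  rownames(out$samples) <- raw$muscle_labels
  out
}

#' Amplitude-normalize envelopes across trials
#'
#' Each muscle is divided by its overall peak amplitude, defined as the
#' maximum of a centered moving-average window (default 50 ms) applied to
#' that muscle's envelope across all supplied trials. Values that exceed 1
#' after division (possible because the peak is measured on the smoothed
#' signal) are clipped to 1.
#'
#' @param envelopes list of [envelope_recording()] objects sharing muscle
#'   order and sampling rate.
#' @param window_ms moving-average window in milliseconds.
#' @return List with `recordings` (normalized trials), `peaks` (per-muscle
#'   peak values used), and `skipped` (labels of all-zero channels left
#'   unnormalized).
#' @export
normalize_amplitude <- function(envelopes, window_ms = 50) {
  stopifnot(length(envelopes) >= 1)
  fs <- envelopes[[1]]$sampling_rate
  labels <- envelopes[[1]]$muscle_labels
  for (e in envelopes) {
    if (!identical(e$muscle_labels, labels) || e$sampling_rate != fs) {
      stop("normalize_amplitude: trials must share muscle order and sampling rate")
    }
  }
  width <- max(1, round(window_ms / 1000 * fs))
  m <- length(labels)
  peaks <- rep(0, m)
  for (e in envelopes) {
    for (i in seq_len(m)) {
      peaks[i] <- max(peaks[i], max(moving_average(e$samples[i, ], width)))
    }
  }
  names(peaks) <- labels
  skipped <- labels[peaks <= 0]
  out <- lapply(envelopes, function(e) {
    for (i in seq_len(m)) {
      if (peaks[i] > 0) e$samples[i, ] <- pmin(e$samples[i, ] / peaks[i], 1)
    }
    e
  })
  list(recordings = out, peaks = peaks, skipped = skipped)
}

#' Detect heel strikes from a heel-marker trajectory
#'
#' The anterior coordinate is low-pass filtered (8 Hz, zero-phase, 4th-order
#' Butterworth) and heel strikes are taken as its local maxima -- on a
#' treadmill the heel is at its most anterior position at initial contact.
#' Peaks must exceed a prominence threshold expressed as a fraction of the
#' coordinate's peak-to-peak range and be separated by a minimum stride time.
#'
#' @param marker data frame or matrix with columns `time`, `x`, `y`, `z`.
#' @param sampling_rate marker sampling rate in Hz.
#' @param anterior_axis which coordinate column points along the direction of
#'   progression (`"x"`, `"y"` or `"z"`); must be stated explicitly.
#' @param prominence_fraction minimum peak prominence as a fraction of the
#'   filtered coordinate's peak-to-peak range (default 0.3).
#' @param min_stride_s minimum time between consecutive strikes in seconds
#'   (default 0.4).
#' @return Numeric vector of strictly increasing event times (seconds).
#' @export
detect_heel_strikes <- function(marker, sampling_rate, anterior_axis,
                                prominence_fraction = 0.3, min_stride_s = 0.4) {
  if (missing(anterior_axis) || is.null(anterior_axis) ||
      !anterior_axis %in% c("x", "y", "z")) {
    stop("detect_heel_strikes: anterior_axis must be one of 'x', 'y', 'z'")
  }
  marker <- as.data.frame(marker)
  stopifnot(all(c("time", anterior_axis) %in% names(marker)))
  tt <- marker$time
  x <- marker[[anterior_axis]]
  lp <- butter_design(4, sampling_rate, low = 8, type = "low")
  xf <- filtfilt_zero_phase(lp$b, lp$a, x, sampling_rate)
  ptp <- diff(range(xf))
  if (ptp <= 0) stop("detect_heel_strikes: constant trajectory, no events")
  idx <- find_peaks(xf, min_prominence = prominence_fraction * ptp,
                    min_distance = max(1, round(min_stride_s * sampling_rate)))
  if (length(idx) < 2) {
    stop("detect_heel_strikes: fewer than 2 events detected, trial rejected")
  }
  # refine the events against the trial's own average cycle template
  # (matched filtering): aligning on the whole cycle shape averages the
  # in-band marker noise that tilts individual peak maxima
  ev <- refine_events_template(xf, idx, sampling_rate)
  tt[1] + ev / sampling_rate
}

# Template-matching event refinement. `idx` are initial peak indices on the
# filtered trajectory `xf`; returns fractional sample positions (0-based).
# Two passes: the second rebuilds the template from the refined events.
# The result is anchored to the template's own sub-sample peak, removing
# the common-mode offset inherited from the noisy initial estimates. Edge
# events are aligned with whatever template portion overlaps the signal
# (at least half a cycle).
refine_events_template <- function(xf, idx, sampling_rate, passes = 1) {
  n <- length(xf)
  pos <- as.numeric(idx - 1)
  if (length(idx) < 3) return(pos)
  half <- round(0.45 * stats::median(diff(idx)))
  lags <- -round(0.15 * sampling_rate):round(0.15 * sampling_rate)
  parab <- function(y0, y1, y2) {
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den < 0) max(-1, min(1, 0.5 * (y0 - y2) / den)) else 0
  }
  centers <- idx
  for (pass in seq_len(passes)) {
    interior <- centers[centers - half >= 1 & centers + half <= n]
    if (length(interior) < 2) break
    tmpl <- rowMeans(vapply(interior, function(i) xf[(i - half):(i + half)],
                            numeric(2 * half + 1)))
    offs <- vapply(centers, function(i) {
      sc <- vapply(lags, function(L) {
        a <- max(1, i + L - half); b <- min(n, i + L + half)
        if (b - a < half) return(-Inf)
        seg <- xf[a:b]
        tm <- tmpl[(a - (i + L - half) + 1):(b - (i + L - half) + 1)]
        suppressWarnings(stats::cor(seg, tm))
      }, numeric(1))
      j <- which.max(sc)
      off <- lags[j]
      if (j > 1 && j < length(lags) && is.finite(sc[j - 1]) && is.finite(sc[j + 1])) {
        off <- off + parab(sc[j - 1], sc[j], sc[j + 1])
      }
      off
    }, numeric(1))
    # anchor: template peak position relative to the window center
    p <- which.max(tmpl)
    u_star <- p - (half + 1)
    if (p > 1 && p < length(tmpl)) {
      u_star <- u_star + parab(tmpl[p - 1], tmpl[p], tmpl[p + 1])
    }
    pos <- (centers - 1) + offs + u_star
    centers <- sort(unique(pmin(pmax(round(pos) + 1, 1), n)))
    pos <- sort(pos)
  }
  pos
}

#' Segment a trial into time-normalized gait cycles
#'
#' Each interval between consecutive events is resampled onto 200
#' equidistant points spanning `[event_i, event_{i+1})` with a cubic spline;
#' the resampled values are clipped to `[0, 1]`. Cycles whose duration falls
#' outside a plausibility gate are dropped (with a message).
#'
#' @param trial normalized [envelope_recording()].
#' @param events heel-strike times in seconds, strictly increasing.
#' @param cycle_gate_s plausible cycle-duration range in seconds.
#' @return List of [gait_cycle_matrix()] objects.
#' @export
segment_and_time_normalize <- function(trial, events, cycle_gate_s = c(0.4, 3)) {
  if (length(events) < 2) stop("segment_and_time_normalize: need >= 2 events")
  fs <- trial$sampling_rate
  n <- ncol(trial$samples)
  tt <- (seq_len(n) - 1) / fs
  if (min(events) < tt[1] - 1e-9 || max(events) > tt[n] + 1e-9) {
    stop("segment_and_time_normalize: events outside trial time span")
  }
  cycles <- list()
  ci <- 0L
  for (i in seq_len(length(events) - 1)) {
    dur <- events[i + 1] - events[i]
    if (dur < cycle_gate_s[1] || dur > cycle_gate_s[2]) {
      message(sprintf("dropping cycle %d: duration %.3f s outside gate [%g, %g]",
                      i, dur, cycle_gate_s[1], cycle_gate_s[2]))
      next
    }
    grid <- events[i] + (0:199) / 200 * dur
    vals <- t(apply(trial$samples, 1, function(y) {
      stats::spline(tt, y, xout = grid, method = "fmm")$y
    }))
    ci <- ci + 1L
    cycles[[ci]] <- gait_cycle_matrix(clip01(vals), cycle_index = ci)
  }
  cycles
}

#' Run the full processing chain on raw trials
#'
#' Convenience wrapper: envelope extraction on every trial, cross-trial
#' amplitude normalization, heel-strike detection per trial, segmentation and
#' time normalization.
#'
#' @param raw_trials list of raw [envelope_recording()] objects.
#' @param markers list of marker tables (one per trial), as accepted by
#'   [detect_heel_strikes()].
#' @param anterior_axis passed to [detect_heel_strikes()].
#' @param ... further arguments to [detect_heel_strikes()].
#' @return List (one element per trial) of lists of [gait_cycle_matrix()].
#' @export
process_trials <- function(raw_trials, markers, anterior_axis, ...) {
  stopifnot(length(raw_trials) == length(markers))
  envs <- lapply(raw_trials, compute_envelope)
  norm <- normalize_amplitude(envs)
  mapply(function(trial, marker) {
    ev <- detect_heel_strikes(marker, trial$sampling_rate,
                              anterior_axis = anterior_axis, ...)
    segment_and_time_normalize(trial, ev)
  }, norm$recordings, markers, SIMPLIFY = FALSE)
}
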