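# Envelope extraction, amplitude normalization, gait segmentation, time
# normalization.

make_rec <- function(x, fs = 2048, labels = "m1") {
  envelope_recording(matrix(x, nrow = length(labels), byrow = TRUE),
                     labels, fs, condition = c(3, 0))
}

test_that("compute_envelope removes DC and rejects bad input", {
  fs <- 2048
  rec <- make_rec(rep(0.5, 4 * fs), fs)
  env <- compute_envelope(rec)
  expect_lt(max(env$samples), 1e-6)

  expect_error(compute_envelope(make_rec(rnorm(100), fs = 500)), "1000 Hz")
  expect_error(compute_envelope(make_rec(rnorm(50), fs)), "too short")
  bad <- make_rec(c(rnorm(5000), NA, rnorm(5000)), fs)
  expect_error(compute_envelope(bad), "non-finite")
})

test_that("pure 100 Hz sinusoid envelope matches rectified-mean prediction and the biquad oracle", {
  fs <- 2048
  tt <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 100 * tt)
  rec <- make_rec(x, fs)
  env <- compute_envelope(rec)$samples[1, ]
  interior <- seq(fs, length(x) - fs)

  # zero-phase band-pass squares the magnitude response at 100 Hz
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  W <- warp(100); W1 <- warp(30); W2 <- warp(300)
  gain_bp <- 1 / sqrt(1 + ((W^2 - sqrt(W1 * W2)^2) / (W * (W2 - W1)))^8)
  expected <- 2 / pi * gain_bp^2              # mean of |sin|, scaled
  expect_lt(max(abs(env[interior] - expected)), 1e-3)

  # full filter path vs independently coded biquad cascade
  sos_bp <- oracle_butter_sos(4, fs, 30, 300, type = "band")
  sos_lp <- oracle_butter_sos(4, fs, 3, type = "low")
  ref <- pmax(oracle_filtfilt(sos_lp,
                              abs(oracle_filtfilt(sos_bp, x, fs)), fs), 0)
  expect_lt(max(abs(env[interior] - ref[interior])), 1e-6)
})

test_that("envelope responds to an in-band burst riding on drift", {
  fs <- 2048
  tt <- seq(0, 6, by = 1 / fs)
  burst <- as.numeric(tt > 2.5 & tt < 3.5)
  x <- 0.5 * sin(2 * pi * 5 * tt) + burst * sin(2 * pi * 100 * tt)
  env <- compute_envelope(make_rec(x, fs))$samples[1, ]
  burst_mean <- mean(env[tt > 2.6 & tt < 3.4])
  base_mean <- mean(env[tt > 0.5 & tt < 2.0])
  expect_gt(burst_mean, 5 * max(base_mean, 1e-9))
})

test_that("zero-phase property: burst peak location is preserved", {
  fs <- 2048
  tt <- seq(0, 4, by = 1 / fs)
  g <- exp(-(tt - 2)^2 / (2 * 0.05^2)) * sin(2 * pi * 100 * tt)
  env <- compute_envelope(make_rec(g, fs))$samples[1, ]
  expect_lt(abs(which.max(env) - which.max(abs(g))), round(0.01 * fs))
})

test_that("normalize_amplitude uses the cross-trial smoothed peak", {
  fs <- 2000
  t1 <- make_rec(rep(0.4, fs))
  out <- normalize_amplitude(list(t1))
  expect_equal(out$recordings[[1]]$samples[1, ], rep(1, fs),
               ignore_attr = TRUE)
  expect_equal(unname(out$peaks), 0.4)

  t2a <- make_rec(rep(0.3, fs)); t2b <- make_rec(rep(0.6, fs))
  out2 <- normalize_amplitude(list(t2a, t2b))
  expect_equal(unname(out2$peaks), 0.6)
  expect_equal(max(out2$recordings[[1]]$samples), 0.5, tolerance = 1e-12)

  # triangular pulse narrower than the 50 ms window: smoothing lowers the peak
  x <- rep(0, fs)
  x[1000:1040] <- c(seq(0, 1, length.out = 21), seq(0.95, 0, length.out = 20))
  out3 <- normalize_amplitude(list(make_rec(x, fs)))
  width <- round(0.05 * fs)
  expect_lt(unname(out3$peaks), max(x))
  expect_equal(unname(out3$peaks), max(brute_moving_average(x, width)),
               tolerance = 1e-12)

  # all-zero channel is flagged and left alone
  z <- envelope_recording(rbind(a = rep(0, fs), b = runif(fs)),
                          c("a", "b"), fs)
  outz <- normalize_amplitude(list(z))
  expect_equal(outz$skipped, "a")
  expect_equal(outz$recordings[[1]]$samples[1, ], rep(0, fs),
               ignore_attr = TRUE)
})

test_that("detect_heel_strikes recovers known event times", {
  fs <- 200
  tt <- seq(0, 12.5, by = 1 / fs)
  x <- 0.15 * cos(2 * pi * tt / 1.2)        # peaks at 0, 1.2, 2.4, ...
  marker <- data.frame(time = tt, x = x, y = 0, z = 0)
  ev <- detect_heel_strikes(marker, fs, anterior_axis = "x")
  expect_gte(length(ev), 10)
  expect_true(all(abs(diff(ev) - 1.2) <= 1 / fs + 1e-9))

  expect_error(detect_heel_strikes(data.frame(time = tt, x = 0, y = 0, z = 0),
                                   fs, anterior_axis = "x"), "constant")
  expect_error(detect_heel_strikes(marker, fs), "anterior_axis")

  # noise inside the 8 Hz analysis band at 10% of the signal amplitude:
  # events still within 2% of the cycle duration (checked on both a sharp
  # sawtooth-like and a smooth sinusoidal trajectory)
  truth <- seq(0, 12, by = 1.2)
  p <- (tt / 1.2) %% 1
  saw <- ifelse(p < 0.65, 0.15 - 0.3 * p / 0.65, -0.15 + 0.3 * (p - 0.65) / 0.35)
  lp <- butter_design(4, fs, low = 8, type = "low")
  for (shape in list(x, saw)) {
    for (sd_i in 1:3) {
      set.seed(sd_i)
      nz <- filtfilt_zero_phase(lp$b, lp$a, rnorm(length(tt)), fs)
      mk <- data.frame(time = tt, x = shape + 0.1 * 0.15 * nz / max(abs(nz)),
                       y = 0, z = 0)
      evn <- detect_heel_strikes(mk, fs, anterior_axis = "x")
      matched <- sapply(evn, function(e) min(abs(e - truth)))
      expect_lt(max(matched), 0.02 * 1.2)
    }
  }
})

test_that("segment_and_time_normalize resamples onto 200 points", {
  fs <- 2048
  n <- 2 * fs
  ramp <- seq(0, 1, length.out = n)
  rec <- make_rec(ramp, fs)
  cyc <- segment_and_time_normalize(rec, c(0, (n - 1) / fs))
  expect_length(cyc, 1)
  expect_equal(ncol(cyc[[1]]$values), 200)
  expect_equal(unname(cyc[[1]]$values[1, 1]), 0, tolerance = 1e-9)
  expect_true(all(diff(cyc[[1]]$values[1, ]) > 0))

  # known Gaussian bump: spline resampling matches the analytic values
  tt <- (seq_len(n) - 1) / fs
  g <- exp(-(tt - 1)^2 / (2 * 0.15^2))
  cycg <- segment_and_time_normalize(make_rec(g, fs), c(0, (n - 1) / fs))
  grid_t <- (0:199) / 200 * ((n - 1) / fs)
  expect_lt(max(abs(cycg[[1]]$values[1, ] - exp(-(grid_t - 1)^2 / (2 * 0.15^2)))),
            1e-3)

  # 3 events -> 2 cycles; implausible durations are dropped
  cyc3 <- segment_and_time_normalize(make_rec(runif(3 * fs), fs),
                                     c(0, 1.1, 2.2))
  expect_length(cyc3, 2)
  expect_message(
    short <- segment_and_time_normalize(make_rec(runif(fs), fs), c(0, 0.1, 0.55)),
    "outside gate")
  expect_length(short, 1)
})

test_that("full chain output respects bounds and band-limited round trip", {
  cfg <- mini_cfg()
  raw <- generate_raw_trial(cfg, 1, 3, 0, n_cycles = 4)
  cycles <- process_trials(list(raw$trial), list(raw$marker),
                           anterior_axis = "x")[[1]]
  expect_gte(length(cycles), 3)
  for (cy in cycles) {
    expect_equal(dim(cy$values), c(15, 200))
    expect_true(all(cy$values >= 0 & cy$values <= 1))
  }

  # resample -> inverse-resample of a smooth cycle reproduces it within 1% RMS
  fs <- 2048
  tt <- (0:(2 * fs - 1)) / fs
  smooth <- 0.5 + 0.4 * sin(2 * pi * tt / 2) + 0.1 * cos(2 * pi * 2 * tt / 2)
  rec <- make_rec(smooth, fs)
  cyc <- segment_and_time_normalize(rec, c(0, (2 * fs - 1) / fs))[[1]]
  back <- stats::spline((0:199) / 200 * 2, cyc$values[1, ], xout = tt,
                        method = "fmm")$y
  expect_lt(sqrt(mean((back - smooth)^2)) / sqrt(mean(smooth^2)), 0.01)
})
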