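# Ground-truth synthetic data generator. Inverts the predictive model as a
# generative one: condition-level weightings follow additive degree<=2
# speed/elevation polynomials around a per-subject perturbed baseline; each
# gait cycle adds weighting jitter and envelope noise. Ground truth
# (weightings, MEPs, primitives) is returned alongside every stage so the
# whole descriptive/predictive pipeline can be validated against it.

#' Default ground-truth configuration
#'
#' A 15-muscle, 4-component world on the 5 speeds x 5 elevations grid.
#' Primitive peak timings follow the canonical locomotion components (early
#' stance ~5%, mid stance ~38%, a bimodal swing component ~72% + ~98%, and
#' late swing ~91% of the gait cycle). Component-dominant muscles carry
#' positive baseline weightings and positive speed trends; elevation trends
#' include quadratic terms for the anti-gravity muscle groups.
#'
#' @param seed master seed; every random stage derives substreams from it.
#' @param n_subjects number of virtual subjects (default 9: 7 training + 2
#'   held out).
#' @param noise_sd floor of the additive envelope noise SD (default 0.02).
#' @param noise_cv signal-dependent noise coefficient: the per-sample noise
#'   SD is `noise_sd + noise_cv * excitation` (default 0.35), reflecting the
#'   signal-dependent variability of EMG envelopes.
#' @param jitter_sd cycle-level weighting jitter SD (default 0.03).
#' @param subject_sd SD of the multiplicative (log-scale) subject baseline
#'   perturbation (default 0.1).
#' @param cycles_mean,cycles_sd,cycles_min gait cycles per condition:
#'   rounded normal draw, truncated below (defaults 17, 2.5, 5).
#' @return A `ground_truth_config` list.
#' @export
default_ground_truth <- function(seed = 1, n_subjects = 9, noise_sd = 0.02,
                                 noise_cv = 0.35, jitter_sd = 0.03,
                                 subject_sd = 0.1,
                                 cycles_mean = 17, cycles_sd = 2.5,
                                 cycles_min = 5) {
  muscles <- default_muscles()
  m <- length(muscles)
  prim <- xp_params(list(
    list(mu = 5.3, sigma = 5),
    list(mu = 37.9, sigma = 7),
    list(mu = 71.9, sigma = 5, mu2 = 97.9, sigma2 = 3, amp2 = 0.9),
    list(mu = 91.3, sigma = 4.5)))

  idx <- function(...) match(c(...), muscles)
  B <- matrix(0.05, m, 4, dimnames = list(muscles, NULL))
  # component 1: weight acceptance -- vasti, glutei (+ light hamstrings)
  B[idx("VastLat", "VastMed", "RFem", "GlutMed", "GlutMax"), 1] <- 0.55
  B[idx("BFem", "Sem", "Sar"), 1] <- 0.10
  # component 2: push-off -- plantarflexors
  B[idx("Sol", "Per", "GastLat", "GastMed"), 2] <- 0.65
  # component 3: early swing -- TA, Sar, Add
  B[idx("TA", "Sar", "Add"), 3] <- 0.65
  # component 4: late swing -- hamstrings (+ TA/abductor co-activation)
  B[idx("BFem", "Sem"), 4] <- 0.90
  B[idx("TA"), 4] <- 0.30
  B[idx("GlutMed"), 4] <- 0.40
  B[idx("TFL"), 4] <- 0.35

  dominant <- B >= 0.2
  speed_a1 <- ifelse(dominant, 0.05, 0)      # per km/h around 3 km/h
  speed_a2 <- matrix(0, m, 4)
  speed_a2[idx("Sol", "GastLat", "GastMed"), 2] <- 0.008
  elev_b1 <- ifelse(dominant, 0.004, 0)      # per % elevation
  elev_b2 <- matrix(0, m, 4)                 # quadratic: uphill and downhill both load
  elev_b2[idx("VastLat", "VastMed", "RFem"), 1] <- 2e-4
  elev_b2[idx("Sol", "GastLat", "GastMed"), 2] <- 2e-4
  dimnames(speed_a1) <- dimnames(speed_a2) <- dimnames(B)
  dimnames(elev_b1) <- dimnames(elev_b2) <- dimnames(B)

  structure(list(
    seed = seed, n_subjects = n_subjects,
    muscle_labels = muscles,
    speeds = 1:5, elevations = c(-20, -10, 0, 10, 20),
    primitives = prim,
    baseline_weightings = B,
    speed_a1 = speed_a1, speed_a2 = speed_a2,
    elev_b1 = elev_b1, elev_b2 = elev_b2,
    noise_sd = noise_sd, noise_cv = noise_cv,
    jitter_sd = jitter_sd, subject_sd = subject_sd,
    cycles_mean = cycles_mean, cycles_sd = cycles_sd, cycles_min = cycles_min),
    class = "ground_truth_config")
}

# Per-subject multiplicative baseline perturbation (log-normal, fixed per
# subject across all conditions).
subject_factors <- function(cfg, subject) {
  set.seed(substream_seed(cfg$seed, "subject", subject))
  matrix(exp(rnorm(length(cfg$baseline_weightings), 0, cfg$subject_sd)),
         nrow(cfg$baseline_weightings), ncol(cfg$baseline_weightings))
}

#' Ground-truth weightings for one subject and condition
#'
#' `clip0( baseline * subject_factor + speed polynomial + elevation
#' polynomial )`; the condition-level truth, before cycle jitter.
#'
#' @param cfg a `ground_truth_config`.
#' @param subject subject index.
#' @param speed,elevation locomotion condition.
#' @return muscles x k matrix.
#' @export
gt_weightings <- function(cfg, subject, speed, elevation) {
  dv <- speed - BASELINE_SPEED
  de <- elevation - BASELINE_ELEVATION
  W <- cfg$baseline_weightings * subject_factors(cfg, subject) +
    cfg$speed_a1 * dv + cfg$speed_a2 * dv^2 +
    cfg$elev_b1 * de + cfg$elev_b2 * de^2
  pmax(W, 0)
}

#' Generate the gait cycles of one subject-condition cell
#'
#' @inheritParams gt_weightings
#' @return List with `cycles` (list of [gait_cycle_matrix()]), `weightings`
#'   (ground-truth condition-level muscles x k), `mep` (ground-truth
#'   muscles x 200 profile `weightings %*% primitives`), and `n_cycles`.
#' @export
generate_condition_cycles <- function(cfg, subject, speed, elevation) {
  W <- gt_weightings(cfg, subject, speed, elevation)  # reseeds internally
  set.seed(substream_seed(cfg$seed, "cond", subject,
                          round(speed * 10), round(elevation * 10)))
  XP <- xp_profile_matrix(cfg$primitives)
  n_cycles <- max(cfg$cycles_min, round(rnorm(1, cfg$cycles_mean, cfg$cycles_sd)))
  m <- nrow(W)
  cycles <- vector("list", n_cycles)
  for (ci in seq_len(n_cycles)) {
    Wc <- pmax(W + matrix(rnorm(length(W), 0, cfg$jitter_sd),
                          nrow(W), ncol(W)), 0)
    Ec <- Wc %*% XP
    # signal-dependent envelope noise: SD floor plus a term proportional to
    # the local excitation level
    sdv <- cfg$noise_sd + (cfg$noise_cv %||% 0) * Ec
    E <- clip01(Ec + matrix(rnorm(m * 200), m, 200) * sdv)
    rownames(E) <- cfg$muscle_labels
    cycles[[ci]] <- gait_cycle_matrix(E, cycle_index = ci)
  }
  mep <- W %*% XP
  rownames(mep) <- cfg$muscle_labels
  list(cycles = cycles, weightings = W, mep = mep, n_cycles = n_cycles)
}

#' Generate a full synthetic dataset
#'
#' All subjects x all grid conditions. Deterministic given `cfg$seed`; each
#' cell draws from its own substream, so subsetting conditions or subjects
#' does not change the remaining cells.
#'
#' @param cfg a `ground_truth_config`.
#' @param subjects subject indices (default all).
#' @param conditions optional data frame with columns `speed`, `elevation`
#'   (default: the full grid).
#' @return Object of class `synthetic_dataset`: list with `config` and
#'   `cells`, a nested list `cells[[subject]][[\"s<v>_e<e>\"]]` of
#'   [generate_condition_cycles()] outputs.
#' @export
generate_dataset <- function(cfg, subjects = seq_len(cfg$n_subjects),
                             conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- expand.grid(speed = cfg$speeds, elevation = cfg$elevations)
  }
  cells <- list()
  for (s in subjects) {
    sub <- list()
    for (i in seq_len(nrow(conditions))) {
      v <- conditions$speed[i]; e <- conditions$elevation[i]
      sub[[cond_key(v, e)]] <- generate_condition_cycles(cfg, s, v, e)
    }
    cells[[as.character(s)]] <- sub
  }
  structure(list(config = cfg, cells = cells), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d subjects x %d conditions (seed %d)\n",
              length(x$cells), length(x$cells[[1]]), x$config$seed))
  invisible(x)
}

cond_key <- function(speed, elevation) sprintf("s%g_e%g", speed, elevation)

parse_cond_key <- function(key) {
  m <- regmatches(key, regexec("^s(-?[0-9.]+)_e(-?[0-9.]+)$", key))[[1]]
  c(speed = as.numeric(m[2]), elevation = as.numeric(m[3]))
}

#' Synthesize a raw-EMG trial plus heel-marker trajectory
#'
#' Emits amplitude-modulated broadband carriers (white noise shaped by the
#' ground-truth excitation envelope, most of whose power lies inside the
#' 30--300 Hz analysis band) so that the full processing chain
#' (band-pass, rectify, low-pass, normalize, segment, time-normalize) can be
#' exercised end to end against known ground truth. The marker's anterior
#' coordinate is a cosine peaking at every heel strike.
#'
#' @inheritParams gt_weightings
#' @param n_cycles number of gait cycles to synthesize (default 10).
#' @param fs sampling rate in Hz (default 2048).
#' @param cycle_s cycle duration in seconds (default: speed-dependent,
#'   `2.2 - 0.2 * speed`).
#' @return List with `trial` (raw [envelope_recording()]), `marker` (data
#'   frame `time, x, y, z`; anterior axis `"x"`), `event_times`, and the
#'   ground-truth `envelope` (muscles x 200 per-cycle template, max 1).
#' @export
generate_raw_trial <- function(cfg, subject, speed, elevation, n_cycles = 10,
                               fs = 2048, cycle_s = NULL) {
  if (is.null(cycle_s)) cycle_s <- 2.2 - 0.2 * speed
  W <- gt_weightings(cfg, subject, speed, elevation)  # reseeds internally
  set.seed(substream_seed(cfg$seed, "raw", subject,
                          round(speed * 10), round(elevation * 10)))
  XP <- xp_profile_matrix(cfg$primitives)
  template <- W %*% XP                        # muscles x 200
  template <- template / max(template)
  m <- nrow(template)
  spc <- round(cycle_s * fs)                  # samples per cycle
  lead <- round(0.5 * fs)                     # padding before first strike
  n <- lead + n_cycles * spc + lead
  tt <- (seq_len(n) - 1) / fs
  event_times <- (lead + (0:n_cycles) * spc) / fs

  # continuous envelope: periodic cubic interpolation of the template
  phase <- ((tt - event_times[1]) / cycle_s) %% 1   # cycle fraction
  gx <- (0:200) / 200
  raw <- matrix(0, m, n)
  for (i in seq_len(m)) {
    gy <- c(template[i, ], template[i, 1])          # close the cycle
    env <- approx(gx, gy, xout = phase)$y
    raw[i, ] <- env * rnorm(n)
  }
  rownames(raw) <- cfg$muscle_labels
  trial <- envelope_recording(raw, cfg$muscle_labels, fs,
                              condition = c(speed, elevation))
  marker <- data.frame(
    time = tt,
    x = 0.15 * cos(2 * pi * (tt - event_times[1]) / cycle_s),
    y = 0, z = tt * 0)
  list(trial = trial, marker = marker,
       event_times = event_times[event_times <= tt[n]],
       envelope = template)
}
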