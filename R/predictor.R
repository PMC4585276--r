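# End-to-end predictive model: generic excitation primitives + weighting
# regression + baseline, applied in subject-generic (SGM) or
# subject-specific (SSM) mode, and the two train/test scenarios.

#' Average subject baselines into a generic baseline
#'
#' Elementwise mean of the per-subject baseline weighting matrices
#' (the subject-generic calibration).
#'
#' @param baselines list of muscles x k matrices, components matched.
#' @return muscles x k matrix.
#' @export
build_generic_baseline <- function(baselines) {
  stopifnot(length(baselines) >= 1)
  d <- dim(baselines[[1]])
  for (b in baselines) {
    if (!identical(dim(b), d)) stop("build_generic_baseline: mismatched ranks")
  }
  Reduce(`+`, baselines) / length(baselines)
}

#' Extract motor components from one cell's gait cycles
#'
#' Concatenates the cycles into a muscles x (200 * cycles) matrix, selects
#' the dimensionality by incremental VAF, averages/normalizes the factors
#' and rescales the weightings, and orders components by peak time (or
#' matches them to a reference set).
#'
#' @param cycles list of [gait_cycle_matrix()].
#' @param vaf_threshold,restarts,seed,max_iter,tol passed to
#'   [select_dimensionality()].
#' @param reference optional reference for [match_components_by_peak()].
#' @return A `motor_component_set`.
#' @export
extract_cell <- function(cycles, vaf_threshold = 0.85, restarts = 50,
                         seed = 1, max_iter = 2000, tol = 1e-6,
                         reference = NULL) {
  X <- do.call(cbind, lapply(cycles, `[[`, "values"))
  cs <- select_dimensionality(X, vaf_threshold = vaf_threshold,
                              restarts = restarts, seed = seed,
                              max_iter = max_iter, tol = tol)
  cs <- normalize_and_scale(cs, length(cycles))
  match_components_by_peak(cs, reference = reference)
}

#' Run the descriptive analysis over a set of dataset cells
#'
#' For each requested subject, the baseline cell (3 km/h, 0 %) is extracted
#' first and ordered by peak time; every other cell is then matched to that
#' subject reference by greedy circular cross-correlation, keeping component
#' order comparable across conditions.
#'
#' @param dataset a `synthetic_dataset` (or any list with the same `cells`
#'   layout).
#' @param subjects subject indices to process.
#' @param conditions data frame `speed`, `elevation` of cells to extract.
#' @param ... passed to [extract_cell()].
#' @param seed master seed; each cell uses a derived substream.
#' @return Nested list `extractions[[as.character(subject)]][[cond_key]]`.
#' @export
extract_components <- function(dataset, subjects, conditions, seed = 1, ...) {
  out <- list()
  for (s in subjects) {
    skey <- as.character(s)
    cell_list <- dataset$cells[[skey]]
    bl_key <- cond_key(BASELINE_SPEED, BASELINE_ELEVATION)
    if (is.null(cell_list[[bl_key]])) {
      stop("extract_components: baseline cell missing for subject ", s)
    }
    ref <- extract_cell(cell_list[[bl_key]]$cycles,
                        seed = substream_seed(seed, "cell", s, 30, 0), ...)
    res <- list()
    res[[bl_key]] <- ref
    for (i in seq_len(nrow(conditions))) {
      v <- conditions$speed[i]; e <- conditions$elevation[i]
      key <- cond_key(v, e)
      if (key == bl_key) next
      res[[key]] <- extract_cell(
        cell_list[[key]]$cycles,
        seed = substream_seed(seed, "cell", s, round(v * 10), round(e * 10)),
        reference = ref, ...)
    }
    out[[skey]] <- res
  }
  out
}

#' Train the predictive model from extracted components
#'
#' Fits Gaussian primitives to every extracted factor and averages them into
#' generic XPs; builds per-subject delta targets from the scaled weightings,
#' averages across subjects, and fits the additive polynomial regression
#' anchored at the generic baseline (the across-subject mean of the
#' baseline-cell weightings).
#'
#' @param extractions output of [extract_components()] for the training
#'   subjects, covering the training conditions (baseline included).
#' @param metadata optional list stored in the model (scenario, seed, ...).
#' @return Object of class `mep_model`.
#' @export
train_predictive_model <- function(extractions, metadata = list()) {
  ranks <- unlist(lapply(extractions, function(sub)
    vapply(sub, `[[`, integer(1), "rank")))
  k <- as.integer(names(sort(table(ranks), decreasing = TRUE))[1])
  usable <- lapply(extractions, function(sub) Filter(function(cs) cs$rank == k, sub))
  dropped <- sum(vapply(extractions, length, integer(1))) -
             sum(vapply(usable, length, integer(1)))
  if (dropped > 0) {
    warning("train_predictive_model: ", dropped,
            " cell(s) with off-modal rank excluded from training")
  }

  fits <- list(); factors <- list()
  for (sub in usable) for (cs in sub) {
    fits[[length(fits) + 1]] <- lapply(seq_len(k), function(j)
      fit_xp(cs$avg_factors[j, ]))
    factors[[length(factors) + 1]] <- cs$avg_factors
  }
  generic_xp <- build_generic_xp(fits, factors)

  bl_key <- cond_key(BASELINE_SPEED, BASELINE_ELEVATION)
  target_list <- list(); baselines <- list()
  for (sub in usable) {
    wl <- lapply(names(sub), function(key) {
      ck <- parse_cond_key(key)
      list(speed = ck[["speed"]], elevation = ck[["elevation"]],
           W = sub[[key]]$weightings)
    })
    target_list[[length(target_list) + 1]] <- build_delta_targets(wl)
    baselines[[length(baselines) + 1]] <- sub[[bl_key]]$weightings
  }
  generic_baseline <- build_generic_baseline(baselines)
  wm <- fit_regression(average_delta_targets(target_list), generic_baseline)

  structure(list(xp = generic_xp, weighting_model = wm,
                 generic_baseline = generic_baseline,
                 muscle_labels = rownames(generic_baseline),
                 rank = k, metadata = metadata),
            class = "mep_model")
}

#' @export
print.mep_model <- function(x, ...) {
  cat(sprintf("<mep_model> %d components, %d muscles\n",
              x$rank, length(x$muscle_labels)))
  print(x$xp)
  print(x$weighting_model)
  invisible(x)
}

#' Predict muscle excitation profiles for a condition
#'
#' Predicted weightings (additive regression) multiplied by the generic
#' excitation primitives evaluated on the 200-point cycle grid:
#' `MEP_m(t) = sum_c W_mc * XP_c(t)`.
#'
#' @param model a `mep_model`.
#' @param speed,elevation locomotion condition.
#' @param mode `"sgm"` (generic baseline) or `"ssm"` (requires
#'   `subject_baseline`).
#' @param subject_baseline muscles x k baseline weightings of the subject
#'   (SSM only).
#' @return Object of class `prediction_result`: `condition`, `mode`,
#'   `weightings` (muscles x k), `mep` (muscles x 200, non-negative),
#'   `clipped`.
#' @export
predict_mep <- function(model, speed, elevation, mode = c("sgm", "ssm"),
                        subject_baseline = NULL) {
  mode <- match.arg(mode)
  if (mode == "ssm" && is.null(subject_baseline)) {
    stop("predict_mep: SSM requires subject_baseline")
  }
  pw <- predict_weightings(model$weighting_model, speed, elevation,
                           baseline_override = if (mode == "ssm") subject_baseline)
  mep <- pw$W %*% xp_profile_matrix(model$xp)
  rownames(mep) <- model$muscle_labels
  structure(list(condition = c(speed = speed, elevation = elevation),
                 mode = mode, weightings = pw$W, mep = mep,
                 clipped = pw$clipped),
            class = "prediction_result")
}

scenario_training_conditions <- function(scenario, cfg) {
  if (scenario == 1) {
    expand.grid(speed = c(1, 3, 5), elevation = c(-20, 0, 20))
  } else {
    expand.grid(speed = cfg$speeds, elevation = cfg$elevations)
  }
}

#' Run a full train/test scenario on a synthetic dataset
#'
#' Scenario 1 trains on the 3 speeds x 3 elevations subset of the training
#' subjects and tests on the remaining 16 conditions; scenario 2 trains on
#' all 25 conditions (known-group testing then covers all 25). Held-out
#' subjects are tested on all conditions (their weighting comparisons are
#' restricted to non-training conditions in scenario 1, mirroring the
#' published bookkeeping). Predictions are compared against the generator's
#' ground-truth registry by default, or against extracted components
#' (`reference = "extracted"`, the full experimental protocol, much
#' slower).
#'
#' @param dataset a `synthetic_dataset` covering the 5 x 5 grid.
#' @param scenario 1 or 2.
#' @param train_subjects,test_subjects subject index vectors (defaults: 7
#'   training, remaining subjects held out).
#' @param modes which prediction modes to evaluate.
#' @param reference `"ground_truth"` or `"extracted"`.
#' @param restarts,vaf_threshold,max_iter,tol factorization settings.
#' @param seed master seed for the extraction substreams.
#' @param precomputed_extractions optional output of [extract_components()]
#'   covering (at least) the training cells of the training subjects and the
#'   baseline cells of all subjects; skips re-extraction.
#' @return List with `model`, `tables` (`weightings`, `mep`, `xp`),
#'   `ranks` (per extracted cell), and `extractions`.
#' @export
run_scenario <- function(dataset, scenario = 1,
                         train_subjects = NULL, test_subjects = NULL,
                         modes = c("sgm", "ssm"),
                         reference = c("ground_truth", "extracted"),
                         restarts = 50, vaf_threshold = 0.85,
                         max_iter = 2000, tol = 1e-6, seed = 1,
                         precomputed_extractions = NULL) {
  reference <- match.arg(reference)
  stopifnot(scenario %in% c(1, 2))
  cfg <- dataset$config
  all_subjects <- as.integer(names(dataset$cells))
  if (is.null(train_subjects)) train_subjects <- utils::head(all_subjects, 7)
  if (is.null(test_subjects)) test_subjects <- setdiff(all_subjects, train_subjects)

  grid <- expand.grid(speed = cfg$speeds, elevation = cfg$elevations)
  train_cond <- scenario_training_conditions(scenario, cfg)
  in_train <- interaction(grid$speed, grid$elevation) %in%
              interaction(train_cond$speed, train_cond$elevation)
  test_cond <- if (scenario == 1) grid[!in_train, , drop = FALSE] else grid
  missing_cells <- !interaction(train_cond$speed, train_cond$elevation) %in%
                   interaction(grid$speed, grid$elevation)
  if (any(missing_cells)) stop("run_scenario: training split not covered by the dataset grid")

  train_keys <- vapply(seq_len(nrow(train_cond)), function(i)
    cond_key(train_cond$speed[i], train_cond$elevation[i]), character(1))
  ex_train <- if (!is.null(precomputed_extractions)) {
    lapply(stats::setNames(as.character(train_subjects),
                           as.character(train_subjects)),
           function(s) precomputed_extractions[[s]][train_keys])
  } else {
    extract_components(dataset, train_subjects, train_cond,
                       seed = seed, vaf_threshold = vaf_threshold,
                       restarts = restarts, max_iter = max_iter, tol = tol)
  }
  model <- train_predictive_model(
    ex_train, metadata = list(scenario = scenario, seed = seed,
                              train_subjects = train_subjects))
  k <- model$rank
  bl_key <- cond_key(BASELINE_SPEED, BASELINE_ELEVATION)

  # SSM baselines: training subjects reuse their training extraction;
  # held-out subjects get a baseline-only extraction.
  ssm_baseline <- list()
  for (s in train_subjects) {
    ssm_baseline[[as.character(s)]] <- ex_train[[as.character(s)]][[bl_key]]$weightings
  }
  ex_test_bl <- if (length(test_subjects) && "ssm" %in% modes) {
    if (!is.null(precomputed_extractions)) {
      lapply(stats::setNames(as.character(test_subjects),
                             as.character(test_subjects)),
             function(s) precomputed_extractions[[s]][bl_key])
    } else {
      extract_components(dataset, test_subjects,
                         data.frame(speed = numeric(0), elevation = numeric(0)),
                         seed = seed, vaf_threshold = vaf_threshold,
                         restarts = restarts, max_iter = max_iter, tol = tol)
    }
  } else list()
  for (s in names(ex_test_bl)) {
    ssm_baseline[[s]] <- ex_test_bl[[s]][[bl_key]]$weightings
  }

  ex_ref <- NULL
  if (reference == "extracted") {
    ex_ref <- extract_components(dataset, c(train_subjects, test_subjects),
                                 test_cond, seed = substream_seed(seed, "ref"),
                                 vaf_threshold = vaf_threshold,
                                 restarts = restarts, max_iter = max_iter,
                                 tol = tol)
  }

  ref_for <- function(s, key) {
    if (reference == "ground_truth") {
      cell <- dataset$cells[[as.character(s)]][[key]]
      list(W = cell$weightings, mep = cell$mep)
    } else {
      cs <- ex_ref[[as.character(s)]][[key]]
      if (is.null(cs) || cs$rank != k) return(NULL)
      list(W = cs$weightings,
           mep = cs$weightings %*% cs$avg_factors)
    }
  }

  wt_rows <- list(); mep_rows <- list()
  eval_subjects <- c(train_subjects, test_subjects)
  for (s in eval_subjects) {
    group <- if (s %in% train_subjects) "known" else "unknown"
    # held-out subjects: all conditions for MEPs, non-training conditions
    # for weighting bookkeeping (scenario 1)
    mep_cond <- if (group == "known") test_cond else grid
    wt_cond <- test_cond
    for (mode in modes) {
      sb <- if (mode == "ssm") ssm_baseline[[as.character(s)]]
      if (mode == "ssm" && is.null(sb)) next
      for (i in seq_len(nrow(mep_cond))) {
        v <- mep_cond$speed[i]; e <- mep_cond$elevation[i]
        key <- cond_key(v, e)
        ref <- ref_for(s, key)
        if (is.null(ref)) next
        pred <- predict_mep(model, v, e, mode = mode, subject_baseline = sb)
        in_wt <- any(wt_cond$speed == v & wt_cond$elevation == e)
        if (in_wt) {
          ws <- weighting_similarity(pred$weightings, ref$W)
          wt_rows[[length(wt_rows) + 1]] <- data.frame(
            subject = s, group = group, mode = mode, speed = v, elevation = e,
            component = ws$component, r = ws$r, rmse = ws$rmse)
        }
        for (mi in seq_len(nrow(pred$mep))) {
          xc <- xcorr_with_shift(ref$mep[mi, ], pred$mep[mi, ])
          mep_rows[[length(mep_rows) + 1]] <- data.frame(
            subject = s, group = group, mode = mode, speed = v, elevation = e,
            muscle = model$muscle_labels[mi], r = xc$r,
            shift_percent = xc$shift_percent,
            rmse = rmse(ref$mep[mi, ], pred$mep[mi, ]))
        }
      }
    }
  }

  # XP table: generic primitives vs ground-truth primitives (or the grand
  # average of extracted factors under reference = "extracted")
  xp_rows <- lapply(seq_len(k), function(j) {
    gen <- evaluate_xp(model$xp, j)
    tru <- if (reference == "ground_truth" && !is.null(cfg$primitives) &&
               length(cfg$primitives$components) >= j) {
      evaluate_xp(cfg$primitives, j)
    } else NULL
    if (is.null(tru)) return(NULL)
    xc <- xcorr_with_shift(tru, gen)
    data.frame(component = j, r = xc$r, shift_percent = xc$shift_percent,
               rmse = rmse(tru, gen))
  })

  ranks <- lapply(ex_train, function(sub) vapply(sub, `[[`, integer(1), "rank"))
  list(model = model,
       tables = list(weightings = do.call(rbind, wt_rows),
                     mep = do.call(rbind, mep_rows),
                     xp = do.call(rbind, xp_rows)),
       ranks = ranks,
       test_conditions = test_cond,
       extractions = ex_train)
}
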