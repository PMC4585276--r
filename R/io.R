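# File formats: delimited trial files (one column per muscle, metadata
# header line), marker trajectories, JSON component sets and model bundles.
# All writes are atomic (temp file + rename) and numerically fixed-format,
# so identical inputs always produce identical bytes.

MODEL_FORMAT_VERSION <- "1.0"

parse_meta_line <- function(line, path) {
  if (!startsWith(line, "#")) {
    stop("parse error in ", path, " line 1: expected metadata line starting with '#'")
  }
  toks <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  kv <- list()
  for (tk in toks) {
    parts <- strsplit(tk, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("parse error in ", path, " line 1: malformed token '", tk, "'")
    kv[[parts[1]]] <- parts[2]
  }
  for (field in c("fs", "speed", "elevation")) {
    if (is.null(kv[[field]])) {
      stop("parse error in ", path, " line 1: missing required field '", field, "'")
    }
    val <- suppressWarnings(as.numeric(kv[[field]]))
    if (is.na(val)) stop("parse error in ", path, " line 1: field '", field, "' is not numeric")
    kv[[field]] <- val
  }
  kv
}

#' Read a trial file
#'
#' Format: one metadata line `# fs=<Hz> speed=<km/h> elevation=<%>`
#' (optionally `cycles=<n> format=cycles200` for pre-normalized cycle
#' data), a header row of muscle labels, then one row per time sample and
#' one column per muscle. Comma or tab delimited (autodetected).
#'
#' @param path file path.
#' @return An [envelope_recording()]; the metadata list is attached as
#'   attribute `"meta"`.
#' @export
read_trial <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2) stop("parse error in ", path, ": file truncated")
  meta <- parse_meta_line(lines[1], path)
  delim <- if (grepl("\t", lines[2])) "\t" else ","
  df <- tryCatch(
    read.table(path, sep = delim, header = TRUE, skip = 1,
               check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  rec <- envelope_recording(t(as.matrix(df)), colnames(df), meta$fs,
                            condition = c(meta$speed, meta$elevation))
  attr(rec, "meta") <- meta
  rec
}

#' Write a trial file
#'
#' @param rec an [envelope_recording()].
#' @param path destination.
#' @param delim `","` or `"\t"`.
#' @param extra_meta named list of extra metadata tokens (e.g.
#'   `list(cycles = 17, format = "cycles200")`).
#' @return The path, invisibly.
#' @export
write_trial <- function(rec, path, delim = ",", extra_meta = list()) {
  meta <- c(list(fs = rec$sampling_rate,
                 speed = rec$condition[["speed"]],
                 elevation = rec$condition[["elevation"]]), extra_meta)
  header <- paste0("# ", paste(names(meta), vapply(meta, function(v)
    if (is.numeric(v)) fmt_num(v) else as.character(v), character(1)),
    sep = "=", collapse = " "))
  body <- t(rec$samples)                          # time x muscles
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(rec$muscle_labels, collapse = delim), con)
    writeLines(apply(body, 1, function(r) paste(fmt_num(r), collapse = delim)),
               con)
  })
}

#' Read a marker trajectory file
#'
#' Delimited text with a header row containing columns `time`, `x`, `y`,
#' `z` (comma or tab, autodetected).
#'
#' @param path file path.
#' @return Data frame with those columns.
#' @export
read_marker <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("parse error in ", path, ": marker file must have columns time, x, y, z")
  }
  df[need]
}

#' Serialize a motor component set to JSON
#'
#' @param cs a `motor_component_set` (after [normalize_and_scale()]).
#' @param path destination; additional metadata (`subject`, `speed`,
#'   `elevation`) may be supplied via `meta`.
#' @param meta named list merged into the JSON object.
#' @return The path, invisibly.
#' @export
save_component_set <- function(cs, path, meta = list()) {
  obj <- c(list(
    format_version = MODEL_FORMAT_VERSION,
    rank = cs$rank, vaf = cs$vaf,
    muscle_labels = cs$muscle_labels,
    weightings = as.vector(t(cs$weightings)),   # row-major
    avg_factors = if (!is.null(cs$avg_factors)) apply(cs$avg_factors, 1, identity, simplify = FALSE),
    component_order = cs$component_order), meta)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
}

#' Read a motor component set from JSON
#'
#' @param path file written by [save_component_set()].
#' @return A `motor_component_set`; extra metadata is attached as attribute
#'   `"meta"`.
#' @export
load_component_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("unsupported component-set format_version: ", obj$format_version)
  }
  m <- length(obj$muscle_labels); k <- obj$rank
  W <- matrix(obj$weightings, m, k, byrow = TRUE,
              dimnames = list(obj$muscle_labels, NULL))
  avg <- if (!is.null(obj$avg_factors)) {
    af <- obj$avg_factors
    if (is.list(af)) do.call(rbind, af)          # list of k 200-vectors
    else if (is.matrix(af) && nrow(af) == k) af  # already k x 200
    else t(as.matrix(af))                        # 200 x k (k = 1 edge case)
  }
  cs <- new_motor_component_set(rank = k, factors = NULL, weightings = W,
                                vaf = obj$vaf, muscle_labels = obj$muscle_labels,
                                avg_factors = avg,
                                component_order = obj$component_order)
  attr(cs, "meta") <- obj[setdiff(names(obj),
    c("format_version", "rank", "vaf", "muscle_labels", "weightings",
      "avg_factors", "component_order"))]
  cs
}

model_schema_check <- function(obj) {
  problems <- character(0)
  need <- c("format_version", "muscle_labels", "rank", "xp", "weighting_model",
            "generic_baseline")
  for (f in need) if (is.null(obj[[f]])) problems <- c(problems, paste0("missing field '", f, "'"))
  if (length(problems)) return(problems)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    return(paste0("unsupported format_version '", obj$format_version, "' (expected ",
                  MODEL_FORMAT_VERSION, ")"))
  }
  wm <- obj$weighting_model
  for (f in c("baseline", "speed_a1", "speed_a2", "elev_a1", "elev_a2",
              "speed_degree", "elev_degree", "baseline_condition")) {
    if (is.null(wm[[f]])) problems <- c(problems, paste0("weighting_model: missing '", f, "'"))
  }
  m <- length(obj$muscle_labels)
  for (f in c("baseline", "speed_a1")) {
    if (!is.null(wm[[f]]) && length(unlist(wm[[f]])) != m * obj$rank) {
      problems <- c(problems, paste0("weighting_model: '", f, "' has wrong length"))
    }
  }
  problems
}

#' Save a predictive model bundle to JSON
#'
#' @param model a `mep_model`.
#' @param path destination.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  wm <- model$weighting_model
  mat_rm <- function(M) as.vector(t(M))  # row-major
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    muscle_labels = model$muscle_labels,
    rank = model$rank,
    xp = model$xp$components,
    weighting_model = list(
      baseline = mat_rm(wm$baseline),
      baseline_condition = unname(wm$baseline_condition),
      speed_a1 = mat_rm(wm$speed_a1), speed_a2 = mat_rm(wm$speed_a2),
      elev_a1 = mat_rm(wm$elev_a1), elev_a2 = mat_rm(wm$elev_a2),
      speed_degree = mat_rm(wm$speed_degree), elev_degree = mat_rm(wm$elev_degree),
      training_levels = wm$training_levels),
    generic_baseline = mat_rm(model$generic_baseline),
    metadata = model$metadata)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  })
}

#' Load a predictive model bundle from JSON
#'
#' Unknown format versions and schema violations are rejected with an
#' itemized message.
#'
#' @param path file written by [save_model()].
#' @return A `mep_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("schema error in ", path, ": ",
                                           conditionMessage(e)))
  problems <- model_schema_check(obj)
  if (length(problems)) {
    stop("schema error in ", path, ":\n  - ", paste(problems, collapse = "\n  - "))
  }
  m <- length(obj$muscle_labels); k <- obj$rank
  unflat <- function(v) matrix(unlist(v), m, k, byrow = TRUE,
                               dimnames = list(obj$muscle_labels, NULL))
  wm <- obj$weighting_model
  xp_components <- if (is.data.frame(obj$xp)) {
    lapply(seq_len(nrow(obj$xp)), function(i) {
      e <- as.list(obj$xp[i, ])
      e[!vapply(e, function(x) is.null(x) || (length(x) == 1 && is.na(x)), logical(1))]
    })
  } else obj$xp
  weighting_model <- structure(list(
    baseline = unflat(wm$baseline),
    baseline_condition = c(speed = wm$baseline_condition[1],
                           elevation = wm$baseline_condition[2]),
    speed_a1 = unflat(wm$speed_a1), speed_a2 = unflat(wm$speed_a2),
    speed_degree = unflat(wm$speed_degree),
    elev_a1 = unflat(wm$elev_a1), elev_a2 = unflat(wm$elev_a2),
    elev_degree = unflat(wm$elev_degree),
    muscle_labels = obj$muscle_labels,
    training_levels = wm$training_levels), class = "weighting_model")
  structure(list(xp = xp_params(xp_components),
                 weighting_model = weighting_model,
                 generic_baseline = unflat(obj$generic_baseline),
                 muscle_labels = obj$muscle_labels,
                 rank = k,
                 metadata = obj$metadata),
            class = "mep_model")
}

#' Write a numeric matrix as delimited text
#'
#' Fixed numeric formatting; row names become the first column when
#' present.
#'
#' @param M matrix.
#' @param path destination.
#' @param delim delimiter (default tab).
#' @return The path, invisibly.
#' @export
write_matrix_file <- function(M, path, delim = "\t") {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    rows <- apply(M, 1, function(r) paste(fmt_num(r), collapse = delim))
    if (!is.null(rownames(M))) rows <- paste(rownames(M), rows, sep = delim)
    writeLines(rows, con)
  })
}

#' Read a numeric matrix written by [write_matrix_file()]
#'
#' @param path file path.
#' @param delim delimiter.
#' @param row_names whether the first column holds row names.
#' @return Numeric matrix.
#' @export
read_matrix_file <- function(path, delim = "\t", row_names = TRUE) {
  df <- read.table(path, sep = delim, header = FALSE)
  if (row_names) {
    rn <- df[[1]]
    M <- as.matrix(df[-1])
    rownames(M) <- rn
  } else {
    M <- as.matrix(df)
  }
  colnames(M) <- NULL
  M
}

# Metric tables: deterministic TSV (numbers fixed-format).
write_table_file <- function(df, path) {
  atomic_write(path, function(tmp) {
    out <- df
    for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

read_config_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
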