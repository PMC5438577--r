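#' Construct and validate a trial
#'
#' A trial is one recording of a walking or one-leg-hop bout: sagittal
#' segment-angle channels (degrees) and/or 3-D marker tracks (metres), the
#' vertical ground-reaction force (newtons), a uniform time base, and
#' metadata identifying subject, task, condition and trial index.
#'
#' Coordinate convention for markers: x is the direction of progression,
#' z is vertical (up), y is mediolateral; right-handed.
#'
#' @param subject_id character scalar identifying the subject.
#' @param task `"gait"` or `"hop"`.
#' @param condition `"sleeve"` or `"none"`.
#' @param trial_index positive integer.
#' @param fs sampling rate in Hz (kinematics and force share one rate).
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing and uniform with step `1/fs`.
#' @param angles named list of numeric vectors (degrees), names among
#'   `"thigh"`, `"shank"`, `"foot"`; may be `NULL` when markers are given.
#' @param markers named list of n-by-3 numeric matrices (metres), one per
#'   marker, columns x/y/z; may be `NULL` when angles are given.
#' @param grf_vertical numeric vector of vertical ground-reaction force in
#'   newtons; baseline-corrected on construction (see
#'   [correct_grf_baseline()]).
#' @return An object of class `crp_trial`.
#' @export
trial <- function(subject_id, task = c("gait", "hop"),
                  condition = c("none", "sleeve"),
                  trial_index = 1L, fs, time,
                  angles = NULL, markers = NULL, grf_vertical) {
  task <- match.arg(task)
  condition <- match.arg(condition)
  obj <- structure(list(
    subject_id = as.character(subject_id),
    task = task,
    condition = condition,
    trial_index = as.integer(trial_index),
    fs = as.numeric(fs),
    time = as.numeric(time),
    angles = angles,
    markers = markers,
    grf_vertical = correct_grf_baseline(as.numeric(grf_vertical))
  ), class = "crp_trial")
  validate_trial(obj)
}

#' @rdname trial
#' @param x a `crp_trial` object.
#' @export
validate_trial <- function(x) {
  stopifnot(inherits(x, "crp_trial"))
  n <- length(x$time)
  if (n < 2L) stop("trial must contain at least 2 samples")
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0)
    stop("fs must be a positive scalar")
  dt <- diff(x$time)
  if (any(dt <= 0)) stop("sampling error: time must be strictly increasing")
  if (max(abs(dt - 1 / x$fs)) > 1e-9)
    stop("sampling error: time step deviates from 1/fs by more than 1e-9 s")
  lens <- c(
    if (!is.null(x$angles)) vapply(x$angles, length, 1L),
    if (!is.null(x$markers)) vapply(x$markers, nrow, 1L),
    length(x$grf_vertical)
  )
  if (any(lens != n))
    stop("all channels must share the time base length (", n, ")")
  if (!is.null(x$angles)) {
    bad <- setdiff(names(x$angles), c("thigh", "shank", "foot"))
    if (length(bad)) stop("unknown angle channel(s): ", paste(bad, collapse = ", "))
    for (a in x$angles) if (!all(is.finite(a))) stop("angles must be finite")
  }
  if (any(x$grf_vertical < 0)) stop("grf_vertical must be >= 0 after baseline correction")
  x
}

#' GRF baseline correction
#'
#' Force plates commonly carry a small static offset. The baseline is taken
#' as the median of the lowest decile of samples, subtracted, and the result
#' clamped at zero so unloaded periods read exactly 0 N.
#'
#' @param grf numeric vector, newtons.
#' @return corrected numeric vector, all values >= 0.
#' @export
correct_grf_baseline <- function(grf) {
  stopifnot(is.numeric(grf), length(grf) >= 1L)
  k <- max(1L, floor(length(grf) / 10))
  base <- stats::median(sort(grf)[seq_len(k)])
  pmax(grf - base, 0)
}

#' @export
print.crp_trial <- function(x, ...) {
  cat(sprintf(
    "<crp_trial> subject %s | %s | %s | trial %d\n  %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, x$task, x$condition, x$trial_index,
    length(x$time), x$fs, length(x$time) / x$fs
  ))
  if (!is.null(x$angles))
    cat("  angles: ", paste(names(x$angles), collapse = ", "), "\n", sep = "")
  if (!is.null(x$markers))
    cat("  markers: ", paste(names(x$markers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- run configuration -----------------------------------------------------

#' Analysis run configuration
#'
#' Bundles the pipeline's fixed constants: low-pass cutoff and filter order,
#' GRF contact threshold, the number of points on the normalized 0-100%
#' base, normalization scope, the SD convention for coordinative
#' variability, and the significance level.
#'
#' @param cutoff_hz low-pass cutoff in Hz (default 6).
#' @param filter_order Butterworth order per pass (default 4; applied
#'   forward and backward for zero phase lag).
#' @param grf_threshold_n contact threshold in newtons (default 10).
#' @param n_points samples on the normalized 0-100% base (default 101).
#' @param normalization_scope `"whole_cycle"` (default) or `"per_phase"`:
#'   whether amplitude normalization uses extrema over the whole normalized
#'   cycle or within each phase window.
#' @param velocity_norm `"minmax"` (default, same rule as the angle) or
#'   `"maxabs"` (divide by max |v|).
#' @param sd_mode `"across_trials"` (default) or `"within_curve"`.
#' @param rms_mode `"ensemble"` (default: RMS of the across-trials mean
#'   curve) or `"per_trial"` (mean of per-trial RMS values).
#' @param gait_cycles `"all"` (default: every complete ipsilateral cycle in
#'   a trial enters the ensemble as a repeat) or `"first"` (first full
#'   cycle only, the single-force-plate-strike convention).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for any stochastic step.
#' @return An object of class `crp_config`.
#' @export
run_config <- function(cutoff_hz = 6, filter_order = 4, grf_threshold_n = 10,
                       n_points = 101,
                       normalization_scope = c("whole_cycle", "per_phase"),
                       velocity_norm = c("minmax", "maxabs"),
                       sd_mode = c("across_trials", "within_curve"),
                       rms_mode = c("ensemble", "per_trial"),
                       gait_cycles = c("all", "first"),
                       alpha = 0.05, seed = 1L) {
  normalization_scope <- match.arg(normalization_scope)
  velocity_norm <- match.arg(velocity_norm)
  sd_mode <- match.arg(sd_mode)
  rms_mode <- match.arg(rms_mode)
  gait_cycles <- match.arg(gait_cycles)
  stopifnot(cutoff_hz > 0, filter_order >= 1, grf_threshold_n > 0)
  if (n_points < 3) stop("n_points must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(
    cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
    grf_threshold_n = grf_threshold_n, n_points = as.integer(n_points),
    normalization_scope = normalization_scope, velocity_norm = velocity_norm,
    sd_mode = sd_mode, rms_mode = rms_mode, gait_cycles = gait_cycles,
    alpha = alpha, seed = as.integer(seed)
  ), class = "crp_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take their defaults; unknown keys are rejected. An absent or
#' empty file yields the default configuration.
#'
#' @param path file path, or `NULL` for all defaults.
#' @return A `crp_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path) || !nzchar(path)) return(run_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(run_config())
  vals <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt) else yaml::yaml.load(txt)
  if (is.null(vals)) return(run_config())
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# ---- trial CSV I/O ---------------------------------------------------------

#' Read a trial from CSV
#'
#' Expects a header row and one sample per line. Recognized columns:
#' `time`, `grf_vertical`, angle columns `angle_thigh`/`angle_shank`/
#' `angle_foot`, and marker columns `<name>_x`/`<name>_y`/`<name>_z`.
#' The sampling rate is inferred from the time column and, when `fs` is
#' supplied in `meta`, checked against it.
#'
#' @param path CSV file path.
#' @param meta named list of trial metadata (`subject_id`, `task`,
#'   `condition`, `trial_index`, optionally `fs`).
#' @return A `crp_trial`.
#' @export
load_trial_csv <- function(path, meta = list()) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("format error: missing required column 'time'")
  if (!"grf_vertical" %in% names(df))
    stop("format error: missing required column 'grf_vertical'")
  tm <- df$time
  if (length(tm) < 2L) stop("format error: need at least 2 samples")
  dt <- diff(tm)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9)
    stop("sampling error: non-uniform time column")
  fs <- 1 / stats::median(dt)
  fs <- round(fs, 6)
  if (!is.null(meta$fs) && abs(meta$fs - fs) > 1e-6 * meta$fs)
    stop("sampling error: inferred fs ", fs, " != metadata fs ", meta$fs)

  ang_cols <- grep("^angle_(thigh|shank|foot)$", names(df), value = TRUE)
  angles <- if (length(ang_cols)) {
    setNames(lapply(ang_cols, function(cn) df[[cn]]),
             sub("^angle_", "", ang_cols))
  } else NULL

  mk_cols <- grep("_(x|y|z)$", names(df), value = TRUE)
  mk_cols <- setdiff(mk_cols, ang_cols)
  markers <- NULL
  if (length(mk_cols)) {
    base <- unique(sub("_(x|y|z)$", "", mk_cols))
    base <- base[vapply(base, function(b)
      all(paste0(b, "_", c("x", "y", "z")) %in% names(df)), TRUE)]
    if (length(base)) {
      markers <- setNames(lapply(base, function(b)
        as.matrix(df[paste0(b, "_", c("x", "y", "z"))])), base)
      markers <- lapply(markers, function(m) {
        colnames(m) <- c("x", "y", "z"); m
      })
    }
  }
  if (is.null(angles) && is.null(markers))
    stop("format error: need angle_{thigh,shank,foot} or <marker>_{x,y,z} columns")

  trial(
    subject_id = meta$subject_id %||% "S01",
    task = meta$task %||% "gait",
    condition = meta$condition %||% "none",
    trial_index = meta$trial_index %||% 1L,
    fs = fs, time = tm, angles = angles, markers = markers,
    grf_vertical = df$grf_vertical
  )
}

#' Write a trial to CSV
#'
#' Inverse of [load_trial_csv()]: the written file round-trips to an
#' identical trial (baseline correction is idempotent).
#'
#' @param x a `crp_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  stopifnot(inherits(x, "crp_trial"))
  df <- data.frame(time = x$time)
  if (!is.null(x$angles))
    for (nm in names(x$angles)) df[[paste0("angle_", nm)]] <- x$angles[[nm]]
  if (!is.null(x$markers))
    for (nm in names(x$markers))
      for (ax in c("x", "y", "z"))
        df[[paste0(nm, "_", ax)]] <- x$markers[[nm]][, ax]
  df$grf_vertical <- x$grf_vertical
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- comparison-table I/O --------------------------------------------------

#' Format a p-value the way result tables print it
#'
#' Three decimals; values below 0.001 render as `"<0.001"`.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Write a condition-comparison table to CSV
#'
#' One row per parameter with mean +/- SD per condition (1 decimal), the
#' test used, its statistic, and the p-value (3 decimals, `<0.001` below
#' 0.001) — the layout of a paired-comparison results table.
#'
#' @param rows data.frame of comparison rows as returned by
#'   [build_comparison_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) stop("rows must be nonempty")
  out <- data.frame(
    parameter = rows$parameter,
    mean_a = sprintf("%.1f", rows$mean_a),
    sd_a = sprintf("%.1f", rows$sd_a),
    mean_b = sprintf("%.1f", rows$mean_b),
    sd_b = sprintf("%.1f", rows$sd_b),
    test = rows$test,
    statistic = sprintf("%.3f", rows$statistic),
    p = format_p(rows$p),
    n = rows$n,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a written comparison table
#'
#' Recovers numeric values at the printed precision; `"<0.001"` parses as
#' `NA` with an attribute-free floor of 0.001 recorded in `p_ceiling`.
#'
#' @param path CSV path written by [write_results_table()].
#' @return data.frame with numeric columns.
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("mean_a", "sd_a", "mean_b", "sd_b", "statistic"))
    df[[cn]] <- as.numeric(df[[cn]])
  df$p_ceiling <- ifelse(df$p == "<0.001", 0.001, NA_real_)
  df$p <- suppressWarnings(as.numeric(df$p))
  df
}
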