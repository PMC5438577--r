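#' Segment angular velocity
#'
#' Finite-difference derivative of an angle series: central differences in
#' the interior, one-sided at the ends, scaled by the sampling rate. The
#' input is expected to be low-pass filtered already.
#'
#' @param theta degrees per sample.
#' @param fs sampling rate, Hz.
#' @return degrees per second, same length as `theta`.
#' @export
compute_velocity <- function(theta, fs) {
  n <- length(theta)
  if (n < 3L) stop("velocity requires at least 3 samples")
  v <- numeric(n)
  v[1] <- (theta[2] - theta[1]) * fs
  v[n] <- (theta[n] - theta[n - 1]) * fs
  i <- 2:(n - 1)
  v[i] <- (theta[i + 1] - theta[i - 1]) * fs / 2
  v
}

#' Min-max amplitude normalization to [-1, 1]
#'
#' `y = 2 (x - min) / (max - min) - 1`, with the extrema taken over `scope`
#' (default: the whole series). The minimum maps to -1 and the maximum to
#' +1 within the scope.
#'
#' @param x numeric samples.
#' @param scope integer indices over which extrema are taken.
#' @return normalized vector, same length as `x`.
#' @export
normalize_amplitude <- function(x, scope = seq_along(x)) {
  lo <- min(x[scope]); hi <- max(x[scope])
  if (hi <= lo) stop("degenerate-signal error: constant over normalization scope")
  2 * (x - lo) / (hi - lo) - 1
}

#' Unwrap a phase sequence given in degrees
#'
#' Adds integer multiples of 360 degrees so that successive differences lie
#' in (-180, 180]; the first sample is unchanged. This removes the
#' artificial discontinuities of a wrapped arctangent phase.
#'
#' @param phi_raw degrees per point.
#' @return unwrapped degrees per point.
#' @export
unwrap_degrees <- function(phi_raw) {
  n <- length(phi_raw)
  if (n == 0L) stop("empty phase sequence")
  d <- diff(phi_raw)
  jumps <- -360 * ceiling((d - 180) / 360)
  phi_raw + c(0, cumsum(jumps))
}

#' Phase portrait of an angle series
#'
#' Pairs the amplitude-normalized angle (x-axis) with the amplitude-
#' normalized velocity (y-axis). Both channels are scaled to [-1, 1]; the
#' velocity may alternatively be scaled by its maximum absolute value.
#'
#' @param theta angle on the normalized time base, degrees.
#' @param v velocity on the same base, degrees/s.
#' @param scope indices over which normalization extrema are taken.
#' @param velocity_norm `"minmax"` or `"maxabs"`.
#' @return list of class `crp_phase_portrait` with `norm_theta`, `norm_v`.
#' @export
phase_portrait <- function(theta, v, scope = seq_along(theta),
                           velocity_norm = c("minmax", "maxabs")) {
  velocity_norm <- match.arg(velocity_norm)
  stopifnot(length(theta) == length(v))
  nt <- normalize_amplitude(theta, scope)
  nv <- if (velocity_norm == "minmax") {
    normalize_amplitude(v, scope)
  } else {
    m <- max(abs(v[scope]))
    if (m == 0) stop("degenerate-signal error: zero velocity throughout")
    v / m
  }
  structure(list(norm_theta = nt, norm_v = nv), class = "crp_phase_portrait")
}

#' Phase angle of a phase portrait
#'
#' The polar angle of (norm_theta, norm_v), taken with the quadrant-aware
#' two-argument arctangent in degrees, then unwrapped so the series is
#' continuous (successive steps within 180 degrees). A (0, 0) sample after
#' the first carries the previous phase forward and is flagged; (0, 0) at
#' the first sample is an error.
#'
#' @param portrait a `crp_phase_portrait`.
#' @return list of class `crp_phase_angle` with `phi` (unwrapped degrees)
#'   and `carried` (indices where the phase was carried forward).
#' @export
compute_phase_angle <- function(portrait) {
  stopifnot(inherits(portrait, "crp_phase_portrait"))
  x <- portrait$norm_theta
  y <- portrait$norm_v
  zero <- x == 0 & y == 0
  if (zero[1]) stop("undefined-phase error: (0,0) at the first sample")
  phi_raw <- atan2(y, x) * 180 / pi
  carried <- which(zero)
  for (i in carried) phi_raw[i] <- phi_raw[i - 1]
  structure(list(phi = unwrap_degrees(phi_raw), carried = carried),
            class = "crp_phase_angle")
}

#' Continuous relative phase between two segments
#'
#' CRP is the phase of the distal segment subtracted from the phase of the
#' proximal segment, pointwise along the normalized cycle. Values near 0
#' indicate in-phase, values near 180 degrees out-of-phase coordination.
#'
#' @param phi_prox proximal-segment `crp_phase_angle` (or numeric phi).
#' @param phi_dist distal-segment `crp_phase_angle` (or numeric phi).
#' @param couple `"TS"` (thigh-shank), `"SF"` (shank-foot) or `"TF"`
#'   (thigh-foot).
#' @return list of class `crp_series` with `couple` and `crp` (degrees).
#' @export
compute_crp <- function(phi_prox, phi_dist, couple = c("TS", "SF", "TF")) {
  couple <- match.arg(couple)
  p <- if (inherits(phi_prox, "crp_phase_angle")) phi_prox$phi else phi_prox
  d <- if (inherits(phi_dist, "crp_phase_angle")) phi_dist$phi else phi_dist
  if (length(p) != length(d)) stop("phase series length mismatch")
  structure(list(couple = couple, crp = p - d), class = "crp_series")
}

#' Per-phase RMS and SD of a set of CRP curves
#'
#' For each phase window: RMS is the root-mean-square of the across-trials
#' ensemble-mean CRP curve over the window's grid points (or, with
#' `rms_mode = "per_trial"`, the mean of per-trial RMS values); SD in
#' `"across_trials"` mode is the per-point sample standard deviation across
#' trials averaged over the window (the deviation-phase convention for
#' coordinative variability), and in `"within_curve"` mode the SD of the
#' mean curve's own points within the window.
#'
#' @param curves list of `crp_series` (or numeric vectors) for the trials
#'   of one subject x task x condition cell; all on the same grid.
#' @param windows a `crp_phase_windows`.
#' @param sd_mode `"across_trials"` or `"within_curve"`.
#' @param rms_mode `"ensemble"` or `"per_trial"`.
#' @return data.frame with one row per phase: `couple`, `phase`, `rms`,
#'   `sd`, `n_trials`.
#' @export
summarize_crp <- function(curves, windows,
                          sd_mode = c("across_trials", "within_curve"),
                          rms_mode = c("ensemble", "per_trial")) {
  sd_mode <- match.arg(sd_mode)
  rms_mode <- match.arg(rms_mode)
  stopifnot(inherits(windows, "crp_phase_windows"), length(curves) >= 1L)
  couple <- if (inherits(curves[[1]], "crp_series")) curves[[1]]$couple else NA_character_
  mat <- do.call(rbind, lapply(curves, function(cv)
    if (inherits(cv, "crp_series")) cv$crp else cv))
  if (ncol(mat) != windows$n_points)
    stop("curves are not on the windows' grid")
  if (sd_mode == "across_trials" && nrow(mat) < 2L)
    stop("across_trials SD needs >= 2 trials; use sd_mode = 'within_curve'")
  mean_curve <- colMeans(mat)
  rows <- lapply(names(windows$windows), function(ph) {
    idx <- window_indices(windows, ph)
    rms <- if (rms_mode == "ensemble") {
      sqrt(mean(mean_curve[idx]^2))
    } else {
      mean(apply(mat[, idx, drop = FALSE], 1, function(r) sqrt(mean(r^2))))
    }
    sdv <- if (sd_mode == "across_trials") {
      mean(apply(mat[, idx, drop = FALSE], 2, stats::sd))
    } else {
      stats::sd(mean_curve[idx])
    }
    data.frame(couple = couple, phase = ph, rms = rms, sd = sdv,
               n_trials = nrow(mat), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
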