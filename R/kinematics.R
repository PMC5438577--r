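#' Sagittal segment angle from two markers
#'
#' The segment angle is the signed angle, in the sagittal (x-z) plane,
#' between the distal-to-proximal segment line and the vertical axis:
#' 0 degrees when the segment is perpendicular to the ground, positive when
#' the proximal end leans forward (counter-clockwise with progression along
#' +x), negative clockwise.
#'
#' @param proximal n-by-2 matrix of (x, z) positions of the proximal marker
#'   (for the foot: the heel).
#' @param distal n-by-2 matrix of (x, z) positions of the distal marker
#'   (for the foot: the 2nd metatarsal head).
#' @param segment `"thigh"`, `"shank"` or `"foot"`.
#' @return list of class `crp_segment_angle` with `segment` and `theta`
#'   (degrees per sample).
#' @export
compute_segment_angle <- function(proximal, distal,
                                  segment = c("thigh", "shank", "foot")) {
  segment <- match.arg(segment)
  proximal <- as.matrix(proximal); distal <- as.matrix(distal)
  stopifnot(ncol(proximal) == 2L, ncol(distal) == 2L,
            nrow(proximal) == nrow(distal))
  dx <- proximal[, 1] - distal[, 1]
  dz <- proximal[, 2] - distal[, 2]
  if (any(dx == 0 & dz == 0))
    stop("degenerate-geometry error: coincident markers")
  theta <- atan2(dx, dz) * 180 / pi
  structure(list(segment = segment, theta = theta),
            class = "crp_segment_angle")
}

#' Landmark values of a normalized segment-angle curve
#'
#' Extracts the initial angle (value at cycle start, i.e. at initial
#' contact), the global minimum and maximum, and — for the foot during gait
#' — the highest local maximum in each half of the cycle (first and second
#' peak, prominence at least 1 degree). Landmarks that do not apply to a
#' segment/task combination are absent. When a required local maximum does
#' not exist, the landmark is `NA` and flagged via the `missing` field
#' rather than erroring.
#'
#' @param theta angle curve on the normalized 0-100% base, degrees.
#' @param segment `"thigh"`, `"shank"` or `"foot"`.
#' @param task `"gait"` or `"hop"`.
#' @return list of class `crp_landmarks` with fields `initial`, `min`, and
#'   task-dependent `max` / `first_peak` / `second_peak`, plus `missing`
#'   (character vector of unfound landmarks).
#' @export
extract_landmarks <- function(theta, segment = c("thigh", "shank", "foot"),
                              task = c("gait", "hop")) {
  segment <- match.arg(segment)
  task <- match.arg(task)
  n <- length(theta)
  stopifnot(n >= 3)
  out <- list(initial = theta[1], min = min(theta))
  missing <- character(0)
  if (task == "hop") {
    out$max <- max(theta)
  } else if (segment == "foot") {
    half <- ceiling(n / 2)
    pk1 <- local_max_value(theta, 1L, half - 1L, prominence = 1)
    pk2 <- local_max_value(theta, half, n, prominence = 1)
    if (is.na(pk1)) missing <- c(missing, "first_peak")
    if (is.na(pk2)) missing <- c(missing, "second_peak")
    out$first_peak <- pk1
    out$second_peak <- pk2
  }
  out$missing <- missing
  structure(out, class = "crp_landmarks")
}

# highest interior local maximum of x within [from, to] with the given
# prominence over the larger of the two flanking minima; NA if none
local_max_value <- function(x, from, to, prominence = 1) {
  idx <- seq.int(max(2L, from), min(length(x) - 1L, to))
  if (!length(idx)) return(NA_real_)
  is_pk <- x[idx] >= x[idx - 1L] & x[idx] >= x[idx + 1L] &
    (x[idx] > x[idx - 1L] | x[idx] > x[idx + 1L])
  pks <- idx[is_pk]
  if (!length(pks)) return(NA_real_)
  keep <- vapply(pks, function(p) {
    lmin <- min(x[seq.int(from, p)])
    rmin <- min(x[seq.int(p, to)])
    x[p] - max(lmin, rmin) >= prominence
  }, TRUE)
  pks <- pks[keep]
  if (!length(pks)) return(NA_real_)
  max(x[pks])
}

#' Spatiotemporal gait parameters for one cycle
#'
#' Computed over the first full gait cycle (ipsilateral IC to next
#' ipsilateral IC): walking velocity from the sacrum marker's forward
#' displacement, stride length from the ipsilateral heel marker's forward
#' travel between successive ICs, cadence assuming symmetric steps
#' (120 / cycle duration in seconds, steps/min), step width as the
#' mediolateral heel separation at the respective ICs, and the stance/swing
#' split of the cycle. Lengths are reported in cm; marker input is metres.
#'
#' @param x a `crp_trial` with markers `sacrum`, `heel_r` (ipsilateral) and
#'   `heel_l`.
#' @param events a `crp_events` for the gait task.
#' @return list of class `crp_spatiotemporal`: `velocity` (cm/s), `cadence`
#'   (steps/min), `step_width` (cm), `stride_length` (cm), `stance_pct`,
#'   `swing_pct`, `stance_time` (s).
#' @export
compute_spatiotemporal <- function(x, events) {
  stopifnot(inherits(x, "crp_trial"), inherits(events, "crp_events"))
  if (x$task != "gait") stop("spatiotemporal parameters are defined for gait")
  need <- c("sacrum", "heel_r", "heel_l")
  miss <- setdiff(need, names(x$markers))
  if (length(miss)) stop("missing marker channel(s): ", paste(miss, collapse = ", "))
  ic <- events$initial_contacts
  if (length(ic) < 2L) stop("insufficient-cycle error: need >= 2 initial contacts")
  ic1 <- ic[1]; ic2 <- ic[2]
  to <- events$toe_offs[events$toe_offs > ic1 & events$toe_offs < ic2]
  if (!length(to)) stop("event-ordering error: no toe off inside the cycle")
  to <- to[1]
  dur <- (ic2 - ic1) / x$fs
  sac <- x$markers$sacrum
  hr <- x$markers$heel_r
  hl <- x$markers$heel_l
  velocity <- unname(sac[ic2, 1] - sac[ic1, 1]) / dur * 100
  stride <- unname(hr[ic2, 1] - hr[ic1, 1]) * 100
  cadence <- 120 / dur
  # contralateral IC nearest mid-cycle for the step-width reading
  icl <- ic1 + round((ic2 - ic1) / 2)
  step_width <- unname(abs(hr[ic1, 2] - hl[icl, 2])) * 100
  stance_pct <- (to - ic1) / (ic2 - ic1) * 100
  structure(list(
    velocity = velocity, cadence = cadence, step_width = step_width,
    stride_length = stride, stance_pct = stance_pct,
    swing_pct = 100 - stance_pct, stance_time = (to - ic1) / x$fs
  ), class = "crp_spatiotemporal")
}

#' @export
print.crp_spatiotemporal <- function(x, ...) {
  cat(sprintf(
    paste0("<crp_spatiotemporal>\n  velocity %.1f cm/s | cadence %.1f steps/min\n",
           "  stride %.1f cm | step width %.1f cm\n",
           "  stance %.1f%% | swing %.1f%% (%.3f s)\n"),
    x$velocity, x$cadence, x$stride_length, x$step_width,
    x$stance_pct, x$swing_pct, x$stance_time))
  invisible(x)
}

#' Segment angles for a trial
#'
#' Returns the trial's angle channels if present, otherwise derives them
#' from the marker set using the default two-marker sagittal mapping
#' (thigh: hip to lateral femoral epicondyle; shank: epicondyle to
#' malleolus; foot: heel to 2nd metatarsal head).
#'
#' @param x a `crp_trial`.
#' @param marker_map named list mapping each segment to its
#'   (proximal, distal) marker names.
#' @return named list of numeric angle vectors (degrees).
#' @export
trial_angles <- function(x, marker_map = list(
                           thigh = c("hip_r", "knee_r"),
                           shank = c("knee_r", "ankle_r"),
                           foot = c("heel_r", "meta2_r"))) {
  stopifnot(inherits(x, "crp_trial"))
  if (!is.null(x$angles) && all(c("thigh", "shank", "foot") %in% names(x$angles)))
    return(x$angles[c("thigh", "shank", "foot")])
  if (is.null(x$markers)) stop("trial has neither full angle set nor markers")
  out <- lapply(names(marker_map), function(seg) {
    mm <- marker_map[[seg]]
    miss <- setdiff(mm, names(x$markers))
    if (length(miss)) stop("missing marker channel(s): ", paste(miss, collapse = ", "))
    p <- x$markers[[mm[1]]][, c("x", "z")]
    d <- x$markers[[mm[2]]][, c("x", "z")]
    compute_segment_angle(p, d, seg)$theta
  })
  names(out) <- names(marker_map)
  out
}
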