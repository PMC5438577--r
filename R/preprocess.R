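#' Zero-lag Butterworth low-pass filter
#'
#' Smooths a kinematic channel with a Butterworth low-pass applied forward
#' and backward (dual pass), which doubles the attenuation and cancels the
#' phase lag. The series is extended by reflection before filtering to
#' suppress start/end transients, then trimmed back.
#'
#' At the cutoff each single pass attenuates by 1/sqrt(2), so the dual-pass
#' gain at cutoff is 0.5.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz; must be below fs/2.
#' @param order Butterworth order per pass (default 4).
#' @return filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 6, order = 4) {
  n <- length(x)
  if (n < 3 * order) stop("filter error: series too short (need >= ", 3 * order, " samples)")
  if (cutoff >= fs / 2) stop("configuration error: cutoff must be < fs/2")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # demean, then pad by odd reflection about the end points, as is standard
  # for zero-phase filtering of finite records; both suppress end transients
  mu <- mean(x)
  xc <- x - mu
  np <- min(n - 1L, 3L * (2L * order + 1L) * 3L)
  head_pad <- 2 * xc[1] - xc[seq(np + 1, 2)]
  tail_pad <- 2 * xc[n] - xc[seq(n - 1, n - np)]
  xe <- c(head_pad, xc, tail_pad)
  ye <- signal::filtfilt(bf, xe)
  ye[seq(np + 1, np + n)] + mu
}

#' Detect foot-contact events from vertical GRF
#'
#' Contact is operationalized as vertical ground-reaction force at or above
#' a threshold (default 10 N, the practical reading of "zero GRF"). An
#' initial contact (IC) is the first sample of each maximal above-threshold
#' run; a toe off (TO) is the first sample after such a run. Runs shorter
#' than 25 ms are ignored (debounce).
#'
#' For gait every contact run is reported (alternating IC/TO). For a hop
#' exactly one take-off followed by one landing is expected: the TO ending
#' the first contact run and the IC starting the next.
#'
#' @param grf baseline-corrected vertical GRF, newtons.
#' @param fs sampling rate, Hz.
#' @param threshold contact threshold, newtons.
#' @param task `"gait"` or `"hop"`.
#' @return An object of class `crp_events`: list with `task`,
#'   `initial_contacts`, `toe_offs` (1-based sample indices).
#' @export
detect_contact_events <- function(grf, fs, threshold = 10, task = c("gait", "hop")) {
  task <- match.arg(task)
  on <- grf >= threshold
  if (!any(on)) stop("no contact detected")
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= ceiling(0.025 * fs)
  ic <- starts[keep]
  to <- ends[keep] + 1L
  if (!length(ic)) stop("no contact detected")
  # a run touching the record end has no observed toe off
  to <- to[to <= length(grf)]
  if (task == "gait") {
    if (length(ic) < 2L)
      stop("insufficient-cycle error: gait requires >= 2 initial contacts")
  } else {
    if (length(ic) < 2L || !length(to))
      stop("hop requires a take-off followed by a landing contact")
    to <- to[1]
    ic <- ic[ic > to][1]
    if (is.na(ic)) stop("no landing contact detected after take-off")
  }
  structure(list(task = task,
                 initial_contacts = as.integer(ic),
                 toe_offs = as.integer(to)),
            class = "crp_events")
}

#' @export
print.crp_events <- function(x, ...) {
  cat(sprintf("<crp_events> %s | IC: %s | TO: %s\n", x$task,
              paste(x$initial_contacts, collapse = ", "),
              paste(x$toe_offs, collapse = ", ")))
  invisible(x)
}

#' Phase windows on the normalized cycle
#'
#' Maps detected events onto the normalized 0-100% base as a partition into
#' movement phases. For gait the cycle runs from one initial contact to the
#' next ipsilateral initial contact, split into stance (IC to TO) and swing
#' (TO to next IC). For a hop the analysis span is split into preflight
#' (start to take-off), flight (take-off to landing), and landing (landing
#' to end). Percent boundaries land on the grid by round-half-up.
#'
#' @param events a `crp_events`.
#' @param trial_span integer length-2 vector: first and last sample index of
#'   the analysis span (for gait, defaults to the first full cycle).
#' @param task `"gait"` or `"hop"`.
#' @param n_points number of grid points on the 0-100% base.
#' @return An object of class `crp_phase_windows`: list with `task` and
#'   `windows`, a named list of half-open index intervals `[lo, hi)` in
#'   1-based grid indices (the last window closes at `n_points + 1`).
#' @export
define_phase_windows <- function(events, trial_span = NULL,
                                 task = c("gait", "hop"), n_points = 101) {
  task <- match.arg(task)
  stopifnot(inherits(events, "crp_events"), n_points >= 3)
  round_half_up <- function(x) floor(x + 0.5)
  pct_to_grid <- function(frac) as.integer(round_half_up(frac * (n_points - 1))) + 1L

  if (task == "gait") {
    ic <- events$initial_contacts
    if (length(ic) < 2L) stop("insufficient-cycle error")
    ic1 <- ic[1]; ic2 <- ic[2]
    to <- events$toe_offs[events$toe_offs > ic1 & events$toe_offs < ic2]
    if (!length(to)) stop("event-ordering error: no toe off inside the cycle")
    to <- to[1]
    span <- trial_span %||% c(ic1, ic2)
    cut <- pct_to_grid((to - span[1]) / (span[2] - span[1]))
    windows <- list(stance = c(1L, cut), swing = c(cut, n_points + 1L))
  } else {
    to <- events$toe_offs[1]
    ic <- events$initial_contacts
    ic <- ic[ic > to][1]
    if (is.na(ic)) stop("event-ordering error: no landing contact after take-off")
    if (is.null(trial_span)) stop("trial_span required for hop windows")
    lo <- trial_span[1]; hi <- trial_span[2]
    if (to <= lo || ic >= hi) stop("event-ordering error: events outside span")
    g_to <- pct_to_grid((to - lo) / (hi - lo))
    g_ic <- pct_to_grid((ic - lo) / (hi - lo))
    windows <- list(preflight = c(1L, g_to), flight = c(g_to, g_ic),
                    landing = c(g_ic, n_points + 1L))
  }
  for (w in windows)
    if (w[2] - w[1] < 2L) stop("phase window shorter than 2 grid points")
  structure(list(task = task, n_points = as.integer(n_points),
                 windows = windows),
            class = "crp_phase_windows")
}

#' Grid indices covered by one phase window
#' @param pw a `crp_phase_windows`.
#' @param phase window name.
#' @return integer vector of 1-based grid indices.
#' @export
window_indices <- function(pw, phase) {
  w <- pw$windows[[phase]]
  if (is.null(w)) stop("unknown phase: ", phase)
  seq.int(w[1], w[2] - 1L)
}

#' Time-normalize a channel onto the 0-100% base
#'
#' Cubic-spline interpolation of the samples inside `span` onto `n_points`
#' equally spaced points covering 0% to 100% of the span. End points are
#' preserved exactly.
#'
#' @param x numeric channel samples (whole trial).
#' @param span integer length-2 vector of first/last sample index.
#' @param n_points grid size (default 101).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, span, n_points = 101) {
  idx <- seq.int(span[1], span[2])
  if (length(idx) < 4L) stop("interpolation error: span must contain >= 4 samples")
  xin <- x[idx]
  out <- stats::spline(x = seq_along(idx), y = xin, method = "fmm",
                       xout = seq(1, length(idx), length.out = n_points))$y
  out[1] <- xin[1]
  out[n_points] <- xin[length(idx)]
  out
}
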