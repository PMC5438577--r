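#' Continuous relative phase analysis of a set of trials
#'
#' Runs the full coordination pipeline on the repeated trials of one
#' subject x task x condition cell: low-pass filtering, velocity, contact
#' events from the vertical GRF, phase segmentation, time normalization to
#' the 0-100% base, phase portraits and unwrapped phase angles per segment,
#' CRP per segment couple (TS thigh-shank, SF shank-foot, TF thigh-foot),
#' and per-phase RMS/SD summaries across trials.
#'
#' For gait every complete ipsilateral cycle (initial contact to the next)
#' found in a trial is analyzed and enters the ensemble as a repeat
#' (`gait_cycles = "first"` in the config restricts the analysis to the
#' first cycle, the single-force-plate-strike convention); for a hop the
#' span runs from movement onset (first sample with any segment angular
#' speed above 5 deg/s, else the trial start) to the end of the recording.
#' When repeats' phase boundaries differ slightly, the ensemble windows
#' are the rounded mean of the per-repeat boundaries.
#'
#' @param trials a `crp_trial` or list of them; all must share task.
#' @param config a `crp_config` (default [run_config()]).
#' @return An object of class `crp_analysis` with components `task`,
#'   `config`, `windows` (ensemble `crp_phase_windows`), `grid` (percent
#'   coordinates), `phase_angles` (per trial, per segment), `crp` (named
#'   list couple -> trials x n_points matrix), `mean_crp` (named list of
#'   mean curves), `summary` (data.frame of per-couple, per-phase RMS/SD),
#'   and `trial_info`.
#' @examples
#' m <- gait_model(n_cycles = 2, jitter_sd = 0, noise_sd = 0)
#' tr <- lapply(1:3, function(i) generate_gait_trial(m, trial_index = i))
#' fit <- crp_analysis(tr)
#' summary(fit)
#' @export
crp_analysis <- function(trials, config = run_config()) {
  if (inherits(trials, "crp_trial")) trials <- list(trials)
  stopifnot(length(trials) >= 1L, inherits(config, "crp_config"))
  task <- trials[[1]]$task
  if (!all(vapply(trials, function(t) t$task, "") == task))
    stop("all trials must share one task")
  if (config$sd_mode == "across_trials" && length(trials) < 2L)
    stop("across_trials SD needs >= 2 trials; use sd_mode = 'within_curve'")

  # one analysis unit ("repeat") per gait cycle / per hop
  per_trial <- list()
  repeat_of_trial <- integer(0)
  for (k in seq_along(trials)) {
    units <- analyze_one_trial(trials[[k]], config = config)
    per_trial <- c(per_trial, units)
    repeat_of_trial <- c(repeat_of_trial, rep.int(k, length(units)))
  }

  # ensemble windows: rounded mean of per-repeat boundaries
  wnames <- names(per_trial[[1]]$windows$windows)
  np <- config$n_points
  bounds <- sapply(per_trial, function(pt)
    vapply(pt$windows$windows, function(w) w[1], 1L))
  bounds <- if (is.matrix(bounds)) round(rowMeans(bounds)) else round(mean(bounds))
  wlist <- list()
  lo <- 1L
  for (i in seq_along(wnames)) {
    hi <- if (i < length(wnames)) as.integer(bounds[i + 1]) else np + 1L
    wlist[[wnames[i]]] <- c(as.integer(lo), hi)
    lo <- hi
  }
  windows <- structure(list(task = task, n_points = np, windows = wlist),
                       class = "crp_phase_windows")

  couples <- list(TS = c("thigh", "shank"), SF = c("shank", "foot"),
                  TF = c("thigh", "foot"))
  crp <- lapply(names(couples), function(cp) {
    segs <- couples[[cp]]
    do.call(rbind, lapply(per_trial, function(pt)
      pt$phi[[segs[1]]] - pt$phi[[segs[2]]]))
  })
  names(crp) <- names(couples)
  mean_crp <- lapply(crp, colMeans)

  summ <- do.call(rbind, lapply(names(crp), function(cp) {
    curves <- lapply(seq_len(nrow(crp[[cp]])), function(i)
      structure(list(couple = cp, crp = crp[[cp]][i, ]), class = "crp_series"))
    summarize_crp(curves, windows, sd_mode = config$sd_mode,
                  rms_mode = config$rms_mode)
  }))
  rownames(summ) <- NULL

  structure(list(
    task = task, config = config, windows = windows,
    grid = seq(0, 100, length.out = np),
    phase_angles = lapply(per_trial, `[[`, "phi"),
    crp = crp, mean_crp = mean_crp, summary = summ,
    trial_info = data.frame(
      subject_id = vapply(trials, `[[`, "", "subject_id")[repeat_of_trial],
      condition = vapply(trials, `[[`, "", "condition")[repeat_of_trial],
      trial_index = vapply(trials, `[[`, 1L, "trial_index")[repeat_of_trial],
      stringsAsFactors = FALSE
    )
  ), class = "crp_analysis")
}

# one trial: filter, velocity, events, then one analysis unit per gait
# cycle (or one per hop); each unit holds phase angles and windows
analyze_one_trial <- function(tr, config) {
  angles <- trial_angles(tr)
  filt <- lapply(angles, lowpass_filter, fs = tr$fs,
                 cutoff = config$cutoff_hz, order = config$filter_order)
  vel <- lapply(filt, compute_velocity, fs = tr$fs)
  events <- detect_contact_events(tr$grf_vertical, tr$fs,
                                  threshold = config$grf_threshold_n,
                                  task = tr$task)
  if (tr$task == "gait") {
    ic <- events$initial_contacts
    n_cyc <- if (config$gait_cycles == "first") 1L else length(ic) - 1L
    lapply(seq_len(n_cyc), function(k) {
      ev_k <- structure(list(
        task = "gait",
        initial_contacts = ic[c(k, k + 1L)],
        toe_offs = events$toe_offs[events$toe_offs > ic[k] &
                                     events$toe_offs < ic[k + 1L]]
      ), class = "crp_events")
      analyze_span(filt, vel, ev_k, span = ic[c(k, k + 1L)],
                   task = "gait", config = config)
    })
  } else {
    speed <- do.call(pmax, lapply(vel, abs))
    onset <- which(speed > 5)[1]
    span <- c(if (is.na(onset)) 1L else onset, length(tr$time))
    list(analyze_span(filt, vel, events, span, task = "hop", config = config))
  }
}

# phase angles per segment over one normalized span
analyze_span <- function(filt, vel, events, span, task, config) {
  windows <- define_phase_windows(events, trial_span = span, task = task,
                                  n_points = config$n_points)
  np <- config$n_points
  phi <- lapply(names(filt), function(seg) {
    th_n <- time_normalize(filt[[seg]], span, np)
    v_n <- time_normalize(vel[[seg]], span, np)
    if (config$normalization_scope == "whole_cycle") {
      pp <- phase_portrait(th_n, v_n, velocity_norm = config$velocity_norm)
      compute_phase_angle(pp)$phi
    } else {
      # per-phase scope: normalize within each window, then stitch
      nt <- numeric(np); nv <- numeric(np)
      for (ph in names(windows$windows)) {
        idx <- window_indices(windows, ph)
        pp <- phase_portrait(th_n, v_n, scope = idx,
                             velocity_norm = config$velocity_norm)
        nt[idx] <- pp$norm_theta[idx]
        nv[idx] <- pp$norm_v[idx]
      }
      pp <- structure(list(norm_theta = nt, norm_v = nv),
                      class = "crp_phase_portrait")
      compute_phase_angle(pp)$phi
    }
  })
  names(phi) <- names(filt)
  list(phi = phi, windows = windows, events = events, span = span)
}

#' @export
print.crp_analysis <- function(x, ...) {
  cat(sprintf("<crp_analysis> %s | %d repeat(s) from %d trial(s) | %d-point base\n",
              x$task, nrow(x$trial_info),
              length(unique(x$trial_info$trial_index)), x$config$n_points))
  cat("  phases:", paste(names(x$windows$windows), collapse = ", "), "\n")
  cat("  per-phase RMS/SD (deg):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.crp_analysis <- function(object, ...) {
  s <- object$summary
  class(s) <- c("summary.crp_analysis", "data.frame")
  s
}

#' @export
print.summary.crp_analysis <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract per-phase RMS/SD as a named vector
#'
#' Names follow `"<rms|sd>_<couple>_<phase>"`, e.g. `rms_TS_stance`.
#' @param object a `crp_analysis`.
#' @param ... unused.
#' @export
coef.crp_analysis <- function(object, ...) {
  s <- object$summary
  stats::setNames(c(s$rms, s$sd),
                  c(paste0("rms_", s$couple, "_", s$phase),
                    paste0("sd_", s$couple, "_", s$phase)))
}

#' Per-trial deviations from the ensemble-mean CRP curve
#'
#' The residual of trial i for a couple is its CRP curve minus the
#' across-trials mean curve; their per-point SD is the coordinative
#' variability the `sd` summary averages per phase.
#'
#' @param object a `crp_analysis`.
#' @param couple `"TS"`, `"SF"` or `"TF"`.
#' @param ... unused.
#' @return trials x n_points matrix of residuals, degrees.
#' @export
residuals.crp_analysis <- function(object, couple = c("TS", "SF", "TF"), ...) {
  couple <- match.arg(couple)
  sweep(object$crp[[couple]], 2, object$mean_crp[[couple]])
}

#' Plot CRP curves over the normalized cycle
#'
#' Draws the ensemble-mean CRP curve per couple with per-trial curves in
#' grey and phase-window boundaries as dashed verticals.
#'
#' @param x a `crp_analysis`.
#' @param couples which couples to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.crp_analysis <- function(x, couples = c("TS", "SF", "TF"), ...) {
  old <- graphics::par(mfrow = c(length(couples), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cp in couples) {
    graphics::matplot(x$grid, t(x$crp[[cp]]), type = "l", lty = 1,
                      col = "grey70", xlab = "cycle (%)",
                      ylab = sprintf("CRP %s (deg)", cp),
                      main = sprintf("CRP %s", cp), ...)
    graphics::lines(x$grid, x$mean_crp[[cp]], lwd = 2)
    for (w in x$windows$windows[-1])
      graphics::abline(v = x$grid[w[1]], lty = 2)
  }
  invisible(x)
}
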