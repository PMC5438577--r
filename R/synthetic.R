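#' Synthetic gait trial model
#'
#' Describes a family of synthetic level-walking trials with known ground
#' truth. Segment angles are sinusoids
#' `theta(t) = offset + amplitude * sin(2 pi t / T + psi + jitter)` whose
#' between-segment phase offsets realize the requested couple lags, so the
#' continuous relative phase of each couple is known analytically
#' (CRP_TS = couple lag ts, CRP_SF = couple lag sf). The vertical GRF is a
#' smooth unimodal bump spanning exactly the stance fraction of each cycle
#' and zero elsewhere; sacrum and heel markers move consistently with the
#' configured stride length and velocity.
#'
#' The cycle duration is `stride_cm / velocity_cms`, quantized to a whole
#' number of samples so cycle boundaries fall on the sampling grid (the
#' stored `velocity_cms` is adjusted accordingly; at 120 Hz the adjustment
#' is below 0.1%). Per-cycle phase jitter (independent across segments) is
#' the ground-truth driver of across-trials CRP variability; white
#' measurement noise is added to the angle channels.
#'
#' Default offsets and amplitudes echo reported healthy-adult sagittal
#' segment-angle ranges during gait; the default stance fraction is 0.62
#' and the default spatiotemporal presets are velocity 136 cm/s and stride
#' 147.2 cm.
#'
#' @param fs sampling rate, Hz.
#' @param n_cycles number of gait cycles per trial (>= 2 so a full
#'   ipsilateral cycle exists). The default 6 matches a pass over a 10 m
#'   walkway at the default stride length.
#' @param velocity_cms walking velocity preset, cm/s.
#' @param stride_cm stride length preset, cm.
#' @param step_width_cm step width preset, cm.
#' @param stance_fraction fraction of the cycle in stance, in (0, 1).
#' @param offsets,amplitudes named numeric vectors (thigh/shank/foot),
#'   degrees.
#' @param couple_lags named vector `c(ts = , sf = )`, degrees: ground-truth
#'   CRP of the thigh-shank and shank-foot couples.
#' @param jitter_sd SD of the per-cycle, per-segment phase perturbation,
#'   degrees.
#' @param noise_sd SD of white measurement noise on angles, degrees.
#' @param grf_peak_n peak vertical GRF, newtons.
#' @param seed base seed; outputs are pure functions of
#'   (model, seed, condition, trial index).
#' @return object of class `crp_gait_model`.
#' @export
gait_model <- function(fs = 120, n_cycles = 6, velocity_cms = 136,
                       stride_cm = 147.2, step_width_cm = 12.1,
                       stance_fraction = 0.62,
                       offsets = c(thigh = 6.65, shank = -20.7, foot = 37.6),
                       amplitudes = c(thigh = 21.55, shank = 38.5, foot = 36.3),
                       couple_lags = c(ts = 30, sf = 40),
                       jitter_sd = 5, noise_sd = 0.5,
                       grf_peak_n = 800, seed = 1L) {
  stopifnot(fs > 0, n_cycles >= 2, velocity_cms > 0, stride_cm > 0,
            stance_fraction > 0, stance_fraction < 1,
            all(amplitudes > 0), jitter_sd >= 0, noise_sd >= 0)
  if (!all(c("thigh", "shank", "foot") %in% names(offsets)) ||
      !all(c("thigh", "shank", "foot") %in% names(amplitudes)))
    stop("offsets and amplitudes need thigh/shank/foot entries")
  if (!all(c("ts", "sf") %in% names(couple_lags)))
    stop("couple_lags needs 'ts' and 'sf' entries")
  cycle_samples <- round(fs * stride_cm / velocity_cms)
  cycle_duration <- cycle_samples / fs
  structure(list(
    fs = fs, n_cycles = as.integer(n_cycles),
    cycle_duration = cycle_duration, cycle_samples = as.integer(cycle_samples),
    velocity_cms = stride_cm / cycle_duration, stride_cm = stride_cm,
    step_width_cm = step_width_cm, stance_fraction = stance_fraction,
    offsets = offsets, amplitudes = amplitudes, couple_lags = couple_lags,
    jitter_sd = jitter_sd, noise_sd = noise_sd, grf_peak_n = grf_peak_n,
    seed = as.integer(seed)
  ), class = "crp_gait_model")
}

#' Synthetic one-leg-hop trial model
#'
#' Three concatenated movement phases — preflight (push-off), flight
#' (airborne, GRF identically zero), landing — with continuous sinusoidal
#' segment-angle trajectories over the whole hop sharing the gait model's
#' lag structure. The preflight GRF starts at body weight and falls
#' smoothly to zero at take-off; the landing GRF rises smoothly from zero
#' at touchdown. Durations are quantized to whole samples.
#'
#' Default angle offsets and amplitudes echo reported one-leg-hop sagittal
#' segment ranges; the default flight time (0.25 s) sits in the reported
#' healthy range.
#'
#' @inheritParams gait_model
#' @param preflight_s,flight_s,landing_s phase durations, seconds.
#' @param body_weight_n standing vertical GRF, newtons.
#' @return object of class `crp_hop_model`.
#' @export
hop_model <- function(fs = 120, preflight_s = 0.5, flight_s = 0.25,
                      landing_s = 0.5,
                      offsets = c(thigh = 13.95, shank = -19.05, foot = 49.85),
                      amplitudes = c(thigh = 19.25, shank = 24.05, foot = 30.35),
                      couple_lags = c(ts = 30, sf = 40),
                      jitter_sd = 5, noise_sd = 0.5,
                      body_weight_n = 700, grf_peak_n = 1100, seed = 1L) {
  stopifnot(fs > 0, preflight_s > 0, flight_s > 0, landing_s > 0,
            all(amplitudes > 0), jitter_sd >= 0, noise_sd >= 0)
  q <- function(s) max(2L, round(s * fs))
  structure(list(
    fs = fs,
    preflight_n = q(preflight_s), flight_n = q(flight_s),
    landing_n = q(landing_s),
    offsets = offsets, amplitudes = amplitudes, couple_lags = couple_lags,
    jitter_sd = jitter_sd, noise_sd = noise_sd,
    body_weight_n = body_weight_n, grf_peak_n = grf_peak_n,
    seed = as.integer(seed)
  ), class = "crp_hop_model")
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-trial seed below 2^31
derive_seed <- function(base, condition, trial_index, extra = 0L) {
  as.integer((as.numeric(base) * 7919 + (condition == "sleeve") * 1299709 +
                as.numeric(trial_index) * 104729 + as.numeric(extra) * 31) %%
               2147483629)
}

# segment base phases realizing the couple lags: CRP couple = psi_distal -
# psi_proximal, so the distal phase leads by the lag
segment_phases <- function(couple_lags) {
  c(thigh = 90,
    shank = 90 + unname(couple_lags["ts"]),
    foot = 90 + unname(couple_lags["ts"]) + unname(couple_lags["sf"]))
}

#' Generate one synthetic gait trial
#'
#' @param model a `crp_gait_model`.
#' @param condition `"none"` or `"sleeve"` (labels the trial; the base
#'   model is condition-independent — condition effects are injected by
#'   [generate_cohort()]).
#' @param trial_index positive integer; distinct indices give independent
#'   jitter/noise draws.
#' @param subject_id subject label.
#' @return a `crp_trial` with angle channels, sacrum/heel markers and GRF.
#' @export
generate_gait_trial <- function(model, condition = c("none", "sleeve"),
                                trial_index = 1L, subject_id = "S01") {
  stopifnot(inherits(model, "crp_gait_model"))
  condition <- match.arg(condition)
  fs <- model$fs
  cs <- model$cycle_samples
  n <- model$n_cycles * cs + 1L
  t <- (seq_len(n) - 1) / fs
  T <- model$cycle_duration
  cyc <- pmin(floor(t / T), model$n_cycles - 1L)  # 0-based cycle index
  phases <- segment_phases(model$couple_lags)

  with_seed(derive_seed(model$seed, condition, trial_index), {
    jit <- matrix(stats::rnorm(model$n_cycles * 3, 0, model$jitter_sd),
                  nrow = model$n_cycles, ncol = 3,
                  dimnames = list(NULL, c("thigh", "shank", "foot")))
    angles <- lapply(c("thigh", "shank", "foot"), function(seg) {
      ph <- (phases[seg] + jit[cyc + 1L, seg]) * pi / 180
      model$offsets[seg] + model$amplitudes[seg] * sin(2 * pi * t / T + ph) +
        stats::rnorm(n, 0, model$noise_sd)
    })
    names(angles) <- c("thigh", "shank", "foot")

    # GRF: smooth unimodal bump over exactly the stance fraction of each cycle
    u <- (t - cyc * T) / (model$stance_fraction * T)
    grf <- ifelse(u > 0 & u < 1,
                  model$grf_peak_n * sqrt(sin(pi * pmin(pmax(u, 0), 1))), 0)

    # markers: sacrum advances at the configured velocity; the ipsilateral
    # heel is stationary in stance and swings forward one stride per cycle
    v_ms <- model$velocity_cms / 100
    stride_m <- model$stride_cm / 100
    sacrum <- cbind(x = v_ms * t, y = 0, z = 1.0)
    sw <- pmin(pmax((u - 1) / (1 / model$stance_fraction - 1), 0), 1)
    heel_x <- stride_m * (cyc + sw^2 * (3 - 2 * sw))
    w <- model$step_width_cm / 100
    heel_r <- cbind(x = heel_x, y = w / 2, z = 0.05)
    heel_l <- cbind(x = heel_x - stride_m / 2, y = -w / 2, z = 0.05)

    trial(subject_id = subject_id, task = "gait", condition = condition,
          trial_index = trial_index, fs = fs, time = t, angles = angles,
          markers = list(sacrum = sacrum, heel_r = heel_r, heel_l = heel_l),
          grf_vertical = grf)
  })
}

#' Generate one synthetic one-leg-hop trial
#'
#' @param model a `crp_hop_model`.
#' @inheritParams generate_gait_trial
#' @return a `crp_trial` with angle channels and GRF (no markers).
#' @export
generate_hop_trial <- function(model, condition = c("none", "sleeve"),
                               trial_index = 1L, subject_id = "S01") {
  stopifnot(inherits(model, "crp_hop_model"))
  condition <- match.arg(condition)
  fs <- model$fs
  np <- model$preflight_n; nf <- model$flight_n; nl <- model$landing_n
  n <- np + nf + nl + 1L
  t <- (seq_len(n) - 1) / fs
  T_tot <- n / fs
  phases <- segment_phases(model$couple_lags)

  with_seed(derive_seed(model$seed, condition, trial_index, extra = 1L), {
    jit <- stats::rnorm(3, 0, model$jitter_sd)
    names(jit) <- c("thigh", "shank", "foot")
    angles <- lapply(c("thigh", "shank", "foot"), function(seg) {
      ph <- (phases[seg] + jit[seg]) * pi / 180
      model$offsets[seg] +
        model$amplitudes[seg] * sin(2 * pi * t / T_tot + ph) +
        stats::rnorm(n, 0, model$noise_sd)
    })
    names(angles) <- c("thigh", "shank", "foot")

    # preflight: body weight falling smoothly to zero at take-off;
    # flight: identically zero; landing: smooth impact bump from zero
    i <- seq_len(n) - 1L
    grf <- numeric(n)
    pre <- i < np
    upre <- i[pre] / np
    grf[pre] <- model$body_weight_n * (1 - upre) * (1 + 2 * upre)
    land <- i >= np + nf
    wl <- (i[land] - np - nf) / nl
    grf[land] <- model$grf_peak_n * sqrt(sin(pi * pmin(wl, 1)))

    trial(subject_id = subject_id, task = "hop", condition = condition,
          trial_index = trial_index, fs = fs, time = t, angles = angles,
          grf_vertical = grf)
  })
}

#' @export
print.crp_gait_model <- function(x, ...) {
  cat(sprintf(
    "<crp_gait_model> %g Hz | %d cycles x %.4f s | stance %.0f%%\n  lags ts=%g sf=%g deg | jitter %g deg | noise %g deg\n",
    x$fs, x$n_cycles, x$cycle_duration, 100 * x$stance_fraction,
    x$couple_lags["ts"], x$couple_lags["sf"], x$jitter_sd, x$noise_sd))
  invisible(x)
}

#' @export
print.crp_hop_model <- function(x, ...) {
  cat(sprintf(
    "<crp_hop_model> %g Hz | preflight %.3f s, flight %.3f s, landing %.3f s\n  lags ts=%g sf=%g deg | jitter %g deg | noise %g deg\n",
    x$fs, x$preflight_n / x$fs, x$flight_n / x$fs, x$landing_n / x$fs,
    x$couple_lags["ts"], x$couple_lags["sf"], x$jitter_sd, x$noise_sd))
  invisible(x)
}

#' Simulate trials from a synthetic model
#'
#' @param object a `crp_gait_model` or `crp_hop_model`.
#' @param nsim number of trials.
#' @param seed optional seed overriding the model's.
#' @param condition trial condition label.
#' @param subject_id subject label.
#' @param ... unused.
#' @return list of `crp_trial` objects.
#' @export
simulate.crp_gait_model <- function(object, nsim = 1, seed = NULL,
                                    condition = "none", subject_id = "S01", ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  lapply(seq_len(nsim), function(i)
    generate_gait_trial(object, condition, i, subject_id))
}

#' @rdname simulate.crp_gait_model
#' @export
simulate.crp_hop_model <- function(object, nsim = 1, seed = NULL,
                                   condition = "none", subject_id = "S01", ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  lapply(seq_len(nsim), function(i)
    generate_hop_trial(object, condition, i, subject_id))
}

#' Generate a synthetic paired-condition cohort
#'
#' Emulates the study design: `n_subjects` subjects, each recorded in both
#' conditions with `n_gait` gait and `n_hop` hop trials per condition.
#' Subject-level model parameters are randomized around the base models'
#' values (couple lags SD 3 deg, offsets SD 1 deg), and named effects are
#' added to the sleeve condition's parameters, so injected effects are
#' known ground truth for recovery testing.
#'
#' Valid effect names: `couple_lag_ts`, `couple_lag_sf`, `jitter_sd`,
#' `velocity_cms` (gait only for the last).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param effect named list/vector of additive sleeve-condition shifts.
#' @param gait_base,hop_base base models.
#' @param n_gait,n_hop trials per condition per subject.
#' @param seed cohort seed.
#' @return list of class `crp_cohort`: per subject, per task, per condition
#'   lists of trials, plus `truth` (per-subject parameter draws).
#' @export
generate_cohort <- function(n_subjects = 11, effect = list(),
                            gait_base = gait_model(), hop_base = hop_model(),
                            n_gait = 5, n_hop = 3, seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  valid <- c("couple_lag_ts", "couple_lag_sf", "jitter_sd", "velocity_cms")
  bad <- setdiff(names(effect), valid)
  if (length(bad)) stop("invalid effect key(s): ", paste(bad, collapse = ", "))
  eff <- function(key) if (key %in% names(effect)) as.numeric(effect[[key]]) else 0

  draws <- with_seed(as.integer(seed) * 7L + 13L, {
    data.frame(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      lag_ts = gait_base$couple_lags["ts"] + stats::rnorm(n_subjects, 0, 3),
      lag_sf = gait_base$couple_lags["sf"] + stats::rnorm(n_subjects, 0, 3),
      off_shift = stats::rnorm(n_subjects, 0, 1),
      seed = sample.int(1000000L, n_subjects)
    )
  })

  subjects <- lapply(seq_len(n_subjects), function(s) {
    d <- draws[s, ]
    one_cond <- function(cond) {
      sh <- if (cond == "sleeve") 1 else 0
      gm <- gait_base
      gm$couple_lags <- c(ts = d$lag_ts + sh * eff("couple_lag_ts"),
                          sf = d$lag_sf + sh * eff("couple_lag_sf"))
      gm$offsets <- gm$offsets + d$off_shift
      gm$jitter_sd <- max(0, gm$jitter_sd + sh * eff("jitter_sd"))
      if (eff("velocity_cms") != 0 && sh == 1) {
        gm <- gait_model(
          fs = gm$fs, n_cycles = gm$n_cycles,
          velocity_cms = gait_base$velocity_cms + eff("velocity_cms"),
          stride_cm = gm$stride_cm, step_width_cm = gm$step_width_cm,
          stance_fraction = gm$stance_fraction, offsets = gm$offsets,
          amplitudes = gm$amplitudes, couple_lags = gm$couple_lags,
          jitter_sd = gm$jitter_sd, noise_sd = gm$noise_sd,
          grf_peak_n = gm$grf_peak_n, seed = gm$seed)
      }
      gm$seed <- d$seed
      hm <- hop_base
      hm$couple_lags <- gm$couple_lags
      hm$jitter_sd <- max(0, hm$jitter_sd + sh * eff("jitter_sd"))
      hm$seed <- d$seed
      list(
        gait = lapply(seq_len(n_gait), function(i)
          generate_gait_trial(gm, cond, i, d$subject)),
        hop = lapply(seq_len(n_hop), function(i)
          generate_hop_trial(hm, cond, i, d$subject))
      )
    }
    list(none = one_cond("none"), sleeve = one_cond("sleeve"))
  })
  names(subjects) <- draws$subject
  structure(list(subjects = subjects, truth = draws, effect = effect),
            class = "crp_cohort")
}

#' @export
print.crp_cohort <- function(x, ...) {
  s1 <- x$subjects[[1]]
  cat(sprintf(
    "<crp_cohort> %d subjects x 2 conditions | %d gait + %d hop trials each\n",
    length(x$subjects), length(s1$none$gait), length(s1$none$hop)))
  if (length(x$effect))
    cat("  injected effects:",
        paste(names(x$effect), unlist(x$effect), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
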