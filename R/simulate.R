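# Ground-truth simulator: phenomenological activation-train model of a
# fibrillating atrium under a 64-electrode basket.  Each electrode carries a
# train of biphasic unipolar wavelets; trains are either intrinsic (planar
# background with per-electrode cycle lengths) or entrained by a focal /
# rotational source while that source is ON.  Far-field QRST, baseline
# drift, white noise and contact-loss artifacts are layered on top.

#' Specify a simulated AF source
#'
#' @param position Grid position `c(s, e)` or a channel/region label
#'   (see [label_to_grid()]).
#' @param kind `"focal"` (divergent wavefronts) or `"rotational"` (rotor).
#' @param cycle_length_ms Source firing period, ms (physiologic AF range
#'   100-350).
#' @param on_fraction Target fraction of time the source is ON. If given,
#'   the mean ON/OFF dwell times are rescaled to this fraction keeping
#'   their sum; if `NULL`, the dwell times are used as-is.
#' @param dwell_on_s,dwell_off_s Mean dwell times of the ON/OFF two-state
#'   switching process (exponential dwells), seconds.
#' @param always_on If `TRUE` the source never switches OFF.
#' @param capture_radius Electrodes within this grid distance of the
#'   source are entrained while it is ON.
#' @param entrain_jitter_ms SD of activation-time jitter under entrainment.
#' @param delta_cl_ms Cycle-length shift imposed on entrained electrodes in
#'   `"shift"` mode.
#' @param entrain_mode `"lock"`: captured electrodes phase-lock to the
#'   source firing train (with conduction delay), collapsing spatial CL
#'   dispersion. `"shift"`: captured electrodes keep their intrinsic cycle
#'   lengths shifted by `delta_cl_ms`, preserving dispersion.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(position, kind = c("focal", "rotational"),
                        cycle_length_ms = 170, on_fraction = NULL,
                        dwell_on_s = 4, dwell_off_s = 9, always_on = FALSE,
                        capture_radius = 3, entrain_jitter_ms = 3,
                        delta_cl_ms = 0, entrain_mode = c("lock", "shift")) {
  kind <- match.arg(kind)
  entrain_mode <- match.arg(entrain_mode)
  if (is.character(position)) position <- label_to_grid(position)
  position <- c(s = position[[1]] %% 8, e = position[[2]])
  stopifnot(position[["e"]] >= 0, position[["e"]] <= 7,
            cycle_length_ms >= 100, cycle_length_ms <= 350,
            dwell_on_s > 0, dwell_off_s >= 0, capture_radius > 0)
  if (!is.null(on_fraction)) {
    stopifnot(on_fraction > 0, on_fraction <= 1)
    total <- dwell_on_s + dwell_off_s
    dwell_on_s <- on_fraction * total
    dwell_off_s <- (1 - on_fraction) * total
    if (on_fraction == 1) always_on <- TRUE
  }
  structure(list(position = position, kind = kind,
                 cycle_length_ms = cycle_length_ms,
                 dwell_on_s = dwell_on_s, dwell_off_s = dwell_off_s,
                 on_fraction = dwell_on_s / (dwell_on_s + dwell_off_s),
                 always_on = always_on || dwell_off_s == 0,
                 capture_radius = capture_radius,
                 entrain_jitter_ms = entrain_jitter_ms,
                 delta_cl_ms = delta_cl_ms, entrain_mode = entrain_mode),
            class = "source_spec")
}

# Alternating-renewal ON intervals with exponential dwells over [t0, t1].
.sim_on_intervals <- function(spec, t0, t1) {
  if (spec$always_on) return(matrix(c(t0, t1), 1, dimnames = list(NULL, c("on", "off"))))
  q <- spec$on_fraction
  state <- runif(1) < q
  t <- t0
  iv <- NULL
  while (t < t1) {
    d <- rexp(1, 1 / (if (state) spec$dwell_on_s else spec$dwell_off_s))
    if (state) iv <- rbind(iv, c(t, min(t + d, t1)))
    t <- t + d
    state <- !state
  }
  if (is.null(iv)) iv <- matrix(numeric(0), 0, 2)
  colnames(iv) <- c("on", "off")
  iv
}

.in_intervals <- function(t, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (k in seq_len(nrow(iv))) out <- out | (t >= iv[k, 1] & t < iv[k, 2])
  out
}

# Asymmetric biphasic atrial wavelet, ~30 ms, unit peak-to-peak, 1 ms grid.
.atrial_wavelet <- function(sample_rate) {
  t <- seq(-15, 15, by = 1000 / sample_rate)
  w <- exp(-((t + 4) / 5)^2) - 1.3 * exp(-((t - 3) / 4)^2)
  w / (max(w) - min(w))
}

# Far-field QRST waveform over -120..+420 ms around the R peak (t = 0),
# unit peak-to-peak.
.qrst_wavelet <- function(sample_rate) {
  t <- seq(-120, 420, by = 1000 / sample_rate)
  w <- exp(-(t / 10)^2) - 0.5 * exp(-((t + 22) / 16)^2) -
    0.45 * exp(-((t - 26) / 14)^2) + 0.33 * exp(-((t - 250) / 55)^2)
  list(t = t, w = w / (max(w) - min(w)), r_offset = which.min(abs(t)))
}

.add_events <- function(x, times_s, kernel, sample_rate, amps = 1) {
  n <- length(x)
  half <- length(kernel)
  amps <- rep_len(amps, length(times_s))
  for (k in seq_along(times_s)) {
    i0 <- round(times_s[k] * sample_rate) + 1L
    idx <- i0:(i0 + half - 1L)
    keep <- idx >= 1L & idx <= n
    if (any(keep)) x[idx[keep]] <- x[idx[keep]] + amps[k] * kernel[keep]
  }
  x
}

#' Simulate a basket recording with ground truth
#'
#' Generates a 64-channel unipolar electrogram recording from a
#' phenomenological activation-train model: planar background activation
#' with per-electrode intrinsic cycle lengths, focal/rotational sources
#' with two-state (exponential-dwell) ON/OFF switching that entrain
#' electrodes within their capture radius, far-field QRST at a regular
#' ventricular rate, baseline drift, white noise and contact-loss
#' artifacts. When capture radii of simultaneously ON sources overlap,
#' the nearer source wins per electrode.
#'
#' @param specs List of [source_spec()] objects (may be empty).
#' @param duration_s Recording length in seconds (>= 4).
#' @param sample_rate Sampling rate, Hz.
#' @param background Named list overriding planar background defaults:
#'   `direction_deg` (propagation direction in the (s, e) plane),
#'   `cl_mean_ms`, `cl_spatial_sd_ms` (spatial SD of intrinsic cycle
#'   lengths), `jitter_ms` (per-activation jitter),
#'   `conduction_ms_per_unit` (inverse conduction velocity, default 25).
#' @param artifacts Named list overriding artifact defaults: `noise_sd_mv`,
#'   `drift_amp_mv`, `drift_freq_hz`, `qrst_amp_mv`, `qrst_rate_bpm`,
#'   `wavelet_amp_mv`, `contact_loss` (channel labels with lost contact).
#' @param rng_seed Integer seed; the same seed and configuration give a
#'   bit-identical recording.
#' @return A list with elements `recording` (a [basket_recording()]) and
#'   `truth` (class `sim_truth`: realized ON intervals, captured-electrode
#'   sets, per-electrode intrinsic cycle lengths, R-peak sample indices,
#'   contact-loss set, and all generator parameters).
#' @export
simulate_recording <- function(specs = list(), duration_s = 60,
                               sample_rate = 1000, background = list(),
                               artifacts = list(), rng_seed = 1L) {
  stopifnot(duration_s >= 4)
  if (inherits(specs, "source_spec")) specs <- list(specs)
  bg <- utils::modifyList(list(direction_deg = 0, cl_mean_ms = 180,
                               cl_spatial_sd_ms = 10, jitter_ms = 5,
                               conduction_ms_per_unit = 25), background)
  ar <- utils::modifyList(list(noise_sd_mv = 0.05, drift_amp_mv = 0.5,
                               drift_freq_hz = 0.2, qrst_amp_mv = 1,
                               qrst_rate_bpm = 60, wavelet_amp_mv = 2,
                               contact_loss = character(0)), artifacts)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(rng_seed))

  pos <- electrode_grid_positions()
  n <- round(duration_s * sample_rate)

  # intrinsic cycle lengths (ms), clamped to the physiologic band
  ecl <- pmin(pmax(rnorm(N_CHANNELS, bg$cl_mean_ms, bg$cl_spatial_sd_ms), 110), 345)

  # planar-wave initial phase: delay along the propagation direction
  th <- bg$direction_deg * pi / 180
  proj <- pos[, 1] * cos(th) + pos[, 2] * sin(th)
  phase0 <- (proj - min(proj)) * bg$conduction_ms_per_unit / 1000

  # realized ON intervals and per-source geometry
  src <- lapply(specs, function(sp) {
    iv <- .sim_on_intervals(sp, -1, duration_s + 1)
    d <- grid_distance(pos, matrix(sp$position, nrow(pos), 2, byrow = TRUE))
    captured <- which(d <= sp$capture_radius)
    ds <- spline_displacement(sp$position[["s"]], pos[, 1])
    de <- pos[, 2] - sp$position[["e"]]
    delay_ms <- if (sp$kind == "focal") {
      d * bg$conduction_ms_per_unit
    } else {
      (atan2(de, ds) %% (2 * pi)) / (2 * pi) * sp$cycle_length_ms +
        d * bg$conduction_ms_per_unit * 0.15
    }
    firings <- if (nrow(iv)) {
      unlist(lapply(seq_len(nrow(iv)), function(k) {
        seq(iv[k, 1] - 0.4, iv[k, 2], by = sp$cycle_length_ms / 1000)
      }))
    } else numeric(0)
    list(spec = sp, on_intervals = iv, captured = captured,
         distance = d, delay_ms = delay_ms, firings = firings)
  })

  atrial <- matrix(0, N_CHANNELS, n)
  wv <- .atrial_wavelet(sample_rate)
  amp_e <- ar$wavelet_amp_mv * runif(N_CHANNELS, 0.8, 1.2)

  for (i in seq_len(N_CHANNELS)) {
    # sources able to capture this electrode, nearest first
    cap <- Filter(function(s) i %in% s$captured, src)
    if (length(cap) > 1L) cap <- cap[order(vapply(cap, function(s) s$distance[i], 0))]
    claimed <- matrix(numeric(0), 0, 2)
    acts <- numeric(0)
    for (s in cap) {
      iv <- s$on_intervals
      if (!nrow(iv)) next
      for (k in seq_len(nrow(iv))) {
        a <- iv[k, 1]; b <- iv[k, 2]
        # skip stretches already claimed by a nearer source
        if (nrow(claimed) && any(a >= claimed[, 1] & b <= claimed[, 2])) next
        sp <- s$spec
        if (sp$entrain_mode == "lock") {
          tt <- s$firings[s$firings >= a - s$delay_ms[i] / 1000 & s$firings < b] +
            s$delay_ms[i] / 1000
        } else {
          p <- (ecl[i] + sp$delta_cl_ms) / 1000
          tt <- a + runif(1) * p
          while (utils::tail(tt, 1) < b) {
            tt <- c(tt, utils::tail(tt, 1) + p +
                      rnorm(1, 0, sp$entrain_jitter_ms / 1000))
          }
        }
        tt <- tt + rnorm(length(tt), 0, sp$entrain_jitter_ms / 1000)
        acts <- c(acts, tt[tt >= a & tt < b])
        claimed <- rbind(claimed, c(a, b))
      }
    }
    # intrinsic train outside claimed intervals
    p <- ecl[i] / 1000
    base <- seq(phase0[i] - 1, duration_s + 0.5, by = p)
    tt <- base + rnorm(length(base), 0, bg$jitter_ms / 1000)
    acts <- c(acts, tt[!.in_intervals(tt, claimed)])
    atrial[i, ] <- .add_events(atrial[i, ], sort(acts) - 0.015, wv,
                               sample_rate, amp_e[i])
  }

  # contact loss: near-field attenuated >= 90 %, far field and noise kept
  loss_idx <- match(ar$contact_loss, basket_channel_labels())
  loss_idx <- loss_idx[!is.na(loss_idx)]
  if (length(loss_idx)) atrial[loss_idx, ] <- atrial[loss_idx, ] * 0.05

  # far-field QRST, coherent across channels
  qw <- .qrst_wavelet(sample_rate)
  beat <- 60 / ar$qrst_rate_bpm
  r_times <- if (ar$qrst_amp_mv > 0) seq(0.35, duration_s - 0.45, by = beat) else numeric(0)
  qrst <- matrix(0, N_CHANNELS, n)
  if (length(r_times)) {
    gain <- ar$qrst_amp_mv * runif(N_CHANNELS, 0.7, 1.3)
    one <- .add_events(numeric(n), r_times - 0.120, qw$w, sample_rate, 1)
    qrst <- matrix(rep(one, each = N_CHANNELS), N_CHANNELS, n) * gain
  }

  tgrid <- seq_len(n) / sample_rate
  drift <- if (ar$drift_amp_mv > 0) {
    f <- ar$drift_freq_hz * runif(N_CHANNELS, 0.7, 1.3)
    ph <- runif(N_CHANNELS, 0, 2 * pi)
    ar$drift_amp_mv * sin(outer(f, tgrid, function(fi, t) 2 * pi * fi * t) + ph)
  } else matrix(0, N_CHANNELS, n)

  noise <- if (ar$noise_sd_mv > 0) {
    matrix(rnorm(N_CHANNELS * n, 0, ar$noise_sd_mv), N_CHANNELS, n)
  } else matrix(0, N_CHANNELS, n)

  sig <- atrial + qrst + drift + noise
  rec <- basket_recording(sig, sample_rate,
                          meta = list(simulated = TRUE, rng_seed = rng_seed))
  truth <- structure(list(
    sources = lapply(src, function(s) list(
      spec = s$spec,
      on_intervals = pmax(pmin(s$on_intervals, duration_s), 0),
      captured = s$captured)),
    electrode_cl_ms = setNames(ecl, basket_channel_labels()),
    qrst_events = round(r_times * sample_rate) + 1L,
    contact_loss = basket_channel_labels()[loss_idx],
    background = bg, artifacts = ar,
    duration_s = duration_s, sample_rate = sample_rate,
    rng_seed = rng_seed
  ), class = "sim_truth")
  list(recording = rec, truth = truth)
}

#' Per-segment ON fraction of each simulated source
#'
#' @param truth A `sim_truth` object.
#' @param hp Hyperparameters (for the segment grid).
#' @return Matrix n_sources x n_segments of the fraction of each segment
#'   during which the source was ON.
#' @export
truth_segment_on <- function(truth, hp = egf_params()) {
  ns <- n_segments_for(truth$duration_s, hp)
  t0 <- (seq_len(ns) - 1) * hp$segment_stride_s
  out <- matrix(0, length(truth$sources), ns)
  for (j in seq_along(truth$sources)) {
    iv <- truth$sources[[j]]$on_intervals
    if (is.null(iv) || nrow(iv) == 0L) next
    for (k in seq_len(ns)) {
      a <- t0[k]; b <- t0[k] + hp$segment_length_s
      ov <- pmax(0, pmin(iv[, 2], b) - pmax(iv[, 1], a))
      out[j, k] <- sum(ov) / hp$segment_length_s
    }
  }
  out
}

#' Simulate an outcome cohort with a recurrence step in final activity
#'
#' Final source activities are drawn uniformly on (0, `activity_max`);
#' 12-month recurrence is Bernoulli(`p_recur_above`) at or above the
#' `step_threshold` and Bernoulli(`p_recur_below`) below it. Event times
#' are uniform over follow-up; non-events are censored at follow-up.
#' Baseline activities are drawn independently from the same range so
#' that all four procedural subgroups are populated.
#'
#' @param n_patients Cohort size (>= 10).
#' @param activity_max Upper bound of the activity distribution (%).
#' @param step_threshold Activity at which recurrence probability steps (%).
#' @param p_recur_above,p_recur_below Recurrence probabilities at/above and
#'   below the step.
#' @param followup_months Follow-up horizon (months).
#' @param rng_seed Integer seed.
#' @return A data.frame with columns `patient_id`, `baseline_activity_pct`,
#'   `final_activity_pct`, `event`, `event_time_months`, `followup_months`.
#' @export
simulate_cohort <- function(n_patients = 200, activity_max = 60,
                            step_threshold = 26.5, p_recur_above = 0.7,
                            p_recur_below = 0.2, followup_months = 12,
                            rng_seed = 1L) {
  stopifnot(n_patients >= 10, p_recur_above >= 0, p_recur_above <= 1,
            p_recur_below >= 0, p_recur_below <= 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(rng_seed))
  final <- runif(n_patients, 0, activity_max)
  baseline <- runif(n_patients, 0, activity_max)
  p <- ifelse(final >= step_threshold, p_recur_above, p_recur_below)
  event <- rbinom(n_patients, 1, p)
  etime <- ifelse(event == 1, runif(n_patients, 0, followup_months),
                  followup_months)
  data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
             baseline_activity_pct = baseline,
             final_activity_pct = final,
             event = as.integer(event),
             event_time_months = etime,
             followup_months = followup_months)
}
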