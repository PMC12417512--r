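# Cycle-length (CL) analysis: per-electrode autocorrelation CL estimates
# with exclusion rules, per-segment spatial statistics, and the
# source-ON/OFF entrainment contrast.

#' Activation envelope of an electrogram for cycle-length analysis
#'
#' Classic envelope preprocessing for atrial CL/dominant-frequency
#' estimation: band-pass to the activation band
#' (`cl_bandpass_low_hz`..`cl_bandpass_high_hz`), full-wave rectify, and
#' low-pass at `cl_envelope_lowpass_hz`. The autocorrelation of the
#' envelope peaks at the local cycle length far more robustly than that
#' of the raw biphasic deflections.
#'
#' @param x Numeric signal vector.
#' @param sample_rate Sampling rate, Hz.
#' @param hp Hyperparameters.
#' @return The envelope signal (same length).
#' @export
cl_envelope <- function(x, sample_rate = 1000, hp = egf_params()) {
  ny <- sample_rate / 2
  bp <- signal::butter(2, c(hp$cl_bandpass_low_hz, min(hp$cl_bandpass_high_hz,
                                                       0.95 * ny)) / ny,
                       type = "pass")
  env <- abs(.filtfilt_pad(bp, x, 200L))
  lp <- signal::butter(2, min(hp$cl_envelope_lowpass_hz / ny, 0.95), type = "low")
  .filtfilt_pad(lp, env, 500L)
}

# Normalized autocorrelation of a demeaned window at integer-sample lags,
# FFT-based, with the bias of the truncated sum removed.
.norm_autocorr <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) return(rep(0, max_lag))
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(max_lag + 1)] / nfft
  lags <- 0:max_lag
  ac <- ac / (n - lags)          # unbiased estimate of the lag covariance
  (ac / ac[1])[-1]
}

#' Cycle length of one electrode window by autocorrelation
#'
#' The normalized autocorrelation is evaluated over lags
#' `[cl_min_ms, cl_max_ms]`; the cycle length is the lag of the highest
#' peak in the band, resolved for harmonics: among local peaks within
#' `cl_peak_tolerance` of the band maximum the shortest lag wins, so a
#' near-tied peak at twice the true period does not inflate the
#' estimate. The electrode window is
#' excluded with reason `"low_amplitude"` when its near-field amplitude is
#' below `cl_amplitude_ratio_min` times the far-field QRST amplitude
#' (checked before the autocorrelation), and with `"low_autocorr"` when
#' the peak autocorrelation is below `cl_autocorr_min`.
#'
#' @param x Numeric vector: one channel window of a preprocessed
#'   (QRST-subtracted) recording. Must be at least `2 * cl_max_ms` long.
#' @param sample_rate Sampling rate, Hz.
#' @param hp Hyperparameters.
#' @param near_field_mv,far_field_mv Amplitudes for the contact rule
#'   (defaults skip the rule).
#' @param is_envelope Set `TRUE` when `x` is already a [cl_envelope()]
#'   signal (used by [spatial_cl_stats()] to filter each channel once).
#' @return A one-row data.frame: `cl_ms`, `peak_autocorr`,
#'   `exclusion_reason` (`"none"`, `"low_autocorr"`, `"low_amplitude"`).
#' @export
electrode_cycle_length <- function(x, sample_rate = 1000, hp = egf_params(),
                                   near_field_mv = 1, far_field_mv = 0,
                                   is_envelope = FALSE) {
  if (length(x) < 2 * hp$cl_max_ms / 1000 * sample_rate) {
    stop("window too short: need at least 2 * cl_max_ms of signal")
  }
  if (near_field_mv < hp$cl_amplitude_ratio_min * far_field_mv) {
    return(data.frame(cl_ms = NA_real_, peak_autocorr = NA_real_,
                      exclusion_reason = "low_amplitude"))
  }
  if (!is_envelope) x <- cl_envelope(x, sample_rate, hp)
  l0 <- round(hp$cl_min_ms / 1000 * sample_rate)
  l1 <- round(hp$cl_max_ms / 1000 * sample_rate)
  rho <- .norm_autocorr(x, l1)
  band <- rho[l0:l1]
  mx <- max(band)
  # local peaks near-tied with the maximum; shortest lag wins
  nb <- length(band)
  is_pk <- band >= c(-Inf, band[-nb]) & band >= c(band[-1], -Inf)
  pk <- which(is_pk & band >= mx - hp$cl_peak_tolerance)[1]
  if (!length(pk) || is.na(pk)) pk <- which.max(band)
  peak <- band[pk]
  if (!is.finite(peak) || peak < hp$cl_autocorr_min) {
    return(data.frame(cl_ms = NA_real_, peak_autocorr = peak,
                      exclusion_reason = "low_autocorr"))
  }
  data.frame(cl_ms = (l0 + pk - 1) / sample_rate * 1000,
             peak_autocorr = peak, exclusion_reason = "none")
}

#' Per-segment spatial cycle-length statistics
#'
#' For every analysis segment (same grid as the flow segments) the CL of
#' each admissible electrode is estimated by autocorrelation over a
#' `cl_window_s` window centred on the segment, and the mean and sample
#' SD across electrodes are reported. Segments with fewer than
#' `cl_min_electrodes` admissible electrodes yield absent (NA) statistics.
#'
#' @param rec The QRST-subtracted `basket_recording`.
#' @param quality A [assess_quality()] mask, or `NULL` for all-admissible.
#' @param hp Hyperparameters.
#' @return A data.frame with one row per segment: `segment_index`,
#'   `mean_cl_ms`, `spatial_sd_ms`, `n_electrodes`.
#' @export
spatial_cl_stats <- function(rec, quality = NULL, hp = egf_params()) {
  stopifnot(inherits(rec, "basket_recording"))
  fs <- rec$sample_rate
  ns <- n_segments_for(rec$duration_s, hp)
  if (ns < 1L) stop("too short: recording shorter than one segment")
  starts <- segment_starts(rec$duration_s, hp)
  n <- ncol(rec$signals)
  half <- hp$cl_window_s / 2
  out <- data.frame(segment_index = seq_len(ns), mean_cl_ms = NA_real_,
                    spatial_sd_ms = NA_real_, n_electrodes = 0L)
  env <- t(apply(rec$signals, 1, cl_envelope, sample_rate = fs, hp = hp))
  for (k in seq_len(ns)) {
    mid <- starts[k] + hp$segment_length_s / 2
    i0 <- max(1L, round((mid - half) * fs) + 1L)
    i1 <- min(n, round((mid + half) * fs))
    cls <- rep(NA_real_, N_CHANNELS)
    for (i in seq_len(N_CHANNELS)) {
      if (!is.null(quality)) {
        if (!quality$admissible[i, k]) next
        m <- electrode_cycle_length(env[i, i0:i1], fs, hp,
                                    near_field_mv = quality$near_field_mv[i, k],
                                    far_field_mv = quality$far_field_mv[i],
                                    is_envelope = TRUE)
      } else {
        m <- electrode_cycle_length(env[i, i0:i1], fs, hp, is_envelope = TRUE)
      }
      if (m$exclusion_reason == "none") cls[i] <- m$cl_ms
    }
    ok <- which(!is.na(cls))
    out$n_electrodes[k] <- length(ok)
    if (length(ok) >= hp$cl_min_electrodes) {
      out$mean_cl_ms[k] <- mean(cls[ok])
      out$spatial_sd_ms[k] <- sd(cls[ok])
    }
  }
  out
}

#' Source-ON vs source-OFF cycle-length contrast
#'
#' Segments are labelled ON when the track's per-segment detection
#' fraction reaches `on_threshold`. The report contrasts mean CL and the
#' spatial CL SD between ON and OFF segments (class aggregates are
#' medians across segments); it is absent (`NULL`) when either class has
#' fewer than 3 segments with valid statistics.
#'
#' @param stats Per-segment statistics from [spatial_cl_stats()].
#' @param track A `source_track` from the same recording (aligned
#'   segment grid).
#' @param on_threshold Detection fraction labelling a segment ON.
#' @return A list `delta_cl_ms` (ON - OFF), `sd_ratio` (SD_ON / SD_OFF),
#'   `pct_sd_reduction` (`100 * (1 - sd_ratio)`), `n_on`, `n_off`,
#'   `sd_on_ms`, `sd_off_ms`, `mean_cl_on_ms`, `mean_cl_off_ms`; or
#'   `NULL` if either class is too small.
#' @export
entrainment_contrast <- function(stats, track,
                                 on_threshold = egf_params()$entrain_on_threshold) {
  det <- track$segment_detection
  if (length(det) != nrow(stats)) {
    stop("segment mismatch: track and CL statistics use different segment grids")
  }
  valid <- !is.na(stats$mean_cl_ms)
  on <- det >= on_threshold & valid
  off <- det < on_threshold & valid
  if (sum(on) < 3 || sum(off) < 3) return(NULL)
  sd_on <- median(stats$spatial_sd_ms[on])
  sd_off <- median(stats$spatial_sd_ms[off])
  cl_on <- median(stats$mean_cl_ms[on])
  cl_off <- median(stats$mean_cl_ms[off])
  list(delta_cl_ms = cl_on - cl_off,
       sd_ratio = sd_on / sd_off,
       pct_sd_reduction = 100 * (1 - sd_on / sd_off),
       n_on = sum(on), n_off = sum(off),
       sd_on_ms = sd_on, sd_off_ms = sd_off,
       mean_cl_on_ms = cl_on, mean_cl_off_ms = cl_off)
}
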