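# Electrogram cleaning: drift removal, ventricular far-field (QRST)
# detection and template subtraction, robust per-channel normalization,
# and per-electrode/per-segment quality assessment.

# Zero-phase filtering with odd-reflection padding (as MATLAB/SciPy
# filtfilt do) so low cutoffs do not ring at the recording edges.
.filtfilt_pad <- function(bf, x, L) {
  n <- length(x)
  L <- min(n - 2L, L)
  pre <- 2 * x[1] - x[(L + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(L + 1):(L + n)]
}

.butter_filtfilt <- function(x, w, type) {
  bf <- signal::butter(2, w, type = type)
  .filtfilt_pad(bf, x, max(50L, ceiling(3 / min(w))))
}

#' High-pass filter a recording to remove baseline drift
#'
#' Per channel: zero-phase spectral (FFT) high-pass on the even (mirror)
#' extension of the signal, zeroing all content below the cutoff. The
#' mirror extension avoids circular-wrap edge artifacts, and the operator
#' is exactly idempotent and phase/length preserving, which an IIR
#' high-pass at such low cutoffs is not.
#'
#' @param rec A [basket_recording()].
#' @param cutoff_hz Cutoff frequency (Hz), `0 < cutoff < sample_rate / 2`.
#' @return The filtered `basket_recording`.
#' @export
highpass_detrend <- function(rec, cutoff_hz = egf_params()$highpass_hz) {
  stopifnot(inherits(rec, "basket_recording"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rec$sample_rate / 2) {
    stop("bad filter spec: cutoff must be in (0, sample_rate/2)")
  }
  n <- ncol(rec$signals)
  n2 <- 2L * n
  freqs <- (seq_len(n2) - 1) / n2 * rec$sample_rate
  keep <- pmin(freqs, rec$sample_rate - freqs) >= cutoff_hz
  out <- t(apply(rec$signals, 1, function(x) {
    x2 <- c(x, rev(x))
    (Re(fft(fft(x2) * keep, inverse = TRUE)) / n2)[seq_len(n)]
  }))
  rec$signals <- out
  dimnames(rec$signals) <- list(rec$channel_labels, NULL)
  rec
}

#' Detect ventricular (R) events from the cross-channel median trace
#'
#' The far-field QRST is coherent across the basket while atrial activity
#' is not, so the cross-channel median isolates the ventricular component;
#' the median trace is additionally band-passed to the QRS band (3-25 Hz),
#' which suppresses residual narrow atrial deflections. R events are peaks
#' exceeding `qrst_detect_mad` robust SDs, with a refractory period of
#' `qrst_refractory_ms` enforced greedily by descending amplitude.
#'
#' @param rec A preprocessed (high-passed) `basket_recording`.
#' @param hp Hyperparameters.
#' @return Strictly increasing integer vector of R-event sample indices
#'   (possibly empty).
#' @export
detect_ventricular_events <- function(rec, hp = egf_params()) {
  stopifnot(inherits(rec, "basket_recording"))
  med <- apply(rec$signals, 2, median)
  ny <- rec$sample_rate / 2
  bf <- signal::butter(2, c(3 / ny, min(25 / ny, 0.99)), type = "pass")
  sm <- .filtfilt_pad(bf, med, as.integer(rec$sample_rate))
  # robust threshold with an absolute far-field amplitude floor: the
  # coherent ventricular far field has a physiologic mV scale, while
  # incoherent atrial activity barely survives the cross-channel median
  thr <- max(hp$qrst_detect_mad * mad(sm), hp$qrst_min_amp_mv)
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  n <- length(sm)
  x <- abs(sm)
  is_peak <- x > thr &
    x >= c(-Inf, x[-n]) &
    x >= c(x[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(integer(0))
  # reject low-amplitude repolarization (T) peaks: keep only peaks
  # commensurate with the largest ventricular deflections
  ref <- quantile(x[cand], 0.9, names = FALSE)
  cand <- cand[x[cand] >= 0.45 * ref]
  cand <- cand[order(x[cand], decreasing = TRUE)]
  refr <- hp$qrst_refractory_ms / 1000 * rec$sample_rate
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Subtract the far-field QRST by event-locked template averaging
#'
#' For each channel the average waveform in a window of
#' `-qrst_pre_ms..+qrst_post_ms` around the detected R events is taken as
#' the far-field template and subtracted at every event. The template
#' peak-to-peak amplitude is recorded per channel as the far-field QRST
#' amplitude used by the quality rules. With fewer than `qrst_min_events`
#' events the template is deemed unreliable and the input is returned
#' unchanged (with `template_unreliable = TRUE`).
#'
#' @param rec A preprocessed `basket_recording`.
#' @param events R-event sample indices from [detect_ventricular_events()].
#' @param hp Hyperparameters.
#' @return A list with `recording` (QRST-subtracted), `far_field_mv`
#'   (named per-channel template peak-to-peak amplitude, mV), `events`,
#'   `template` (64 x window matrix) and `template_unreliable`.
#' @export
subtract_qrst <- function(rec, events, hp = egf_params()) {
  stopifnot(inherits(rec, "basket_recording"))
  n <- ncol(rec$signals)
  pre <- round(hp$qrst_pre_ms / 1000 * rec$sample_rate)
  post <- round(hp$qrst_post_ms / 1000 * rec$sample_rate)
  full <- events[events - pre >= 1 & events + post <= n]
  if (length(full) < hp$qrst_min_events) {
    if (length(events)) {
      warning("fewer than ", hp$qrst_min_events,
              " usable ventricular events; QRST template unreliable, ",
              "recording returned unchanged")
    }
    return(list(recording = rec,
                far_field_mv = setNames(rep(0, N_CHANNELS), rec$channel_labels),
                events = events, template = NULL,
                template_unreliable = TRUE))
  }
  offs <- -pre:post
  # 64 x length(offs) template: mean across events
  tmpl <- matrix(0, N_CHANNELS, length(offs))
  for (ev in full) tmpl <- tmpl + rec$signals[, ev + offs, drop = FALSE]
  tmpl <- tmpl / length(full)
  out <- rec$signals
  for (ev in events) {
    idx <- ev + offs
    keep <- idx >= 1 & idx <= n
    out[, idx[keep]] <- out[, idx[keep]] - tmpl[, keep, drop = FALSE]
  }
  rec$signals <- out
  far <- apply(tmpl, 1, function(z) max(z) - min(z))
  list(recording = rec,
       far_field_mv = setNames(far, rec$channel_labels),
       events = events, template = tmpl, template_unreliable = FALSE)
}

#' Normalize channels to unit robust amplitude
#'
#' Each channel is divided by its median absolute deviation (scaled MAD),
#' so channels contribute comparably to the interpolated image regardless
#' of contact-dependent gain. All-zero channels are left at zero and
#' flagged in `meta$zero_channels`.
#'
#' @param rec A `basket_recording`.
#' @return The normalized `basket_recording`.
#' @export
normalize_channels <- function(rec) {
  stopifnot(inherits(rec, "basket_recording"))
  s <- apply(rec$signals, 1, mad)
  zero <- s == 0 | !is.finite(s)
  s[zero] <- 1
  rec$signals <- rec$signals / s
  rec$meta$zero_channels <- rec$channel_labels[zero]
  rec
}

#' Assess per-electrode, per-segment signal quality
#'
#' An electrode is admissible in a segment iff its near-field amplitude is
#' at least `cl_amplitude_ratio_min` times its far-field QRST amplitude
#' (electrode-contact rule) and the fraction of signal RMS above
#' `quality_hf_cutoff_hz` is below `quality_max_hf_ratio` (noise rule).
#' Near-field amplitude is a robust per-segment peak-to-peak (twice the
#' 99th percentile of the absolute deviation from the segment median) of
#' the QRST-subtracted signal.
#'
#' @param rec The QRST-subtracted (not yet normalized) `basket_recording`.
#' @param far_field_mv Per-channel far-field amplitudes from
#'   [subtract_qrst()].
#' @param hp Hyperparameters.
#' @return An object of class `quality_mask`: `admissible` (64 x
#'   n_segments logical), `near_field_mv` (64 x n_segments),
#'   `far_field_mv` (length 64), `hf_ratio` (64 x n_segments).
#' @export
assess_quality <- function(rec, far_field_mv = rep(0, 64), hp = egf_params()) {
  stopifnot(inherits(rec, "basket_recording"))
  ns <- n_segments_for(rec$duration_s, hp)
  if (ns < 1L) stop("too short: recording shorter than one segment")
  fs <- rec$sample_rate
  wh <- min(hp$quality_hf_cutoff_hz / (fs / 2), 0.99)
  hf <- t(apply(rec$signals, 1, .butter_filtfilt, w = wh, type = "high"))
  starts <- segment_starts(rec$duration_s, hp)
  near <- matrix(0, N_CHANNELS, ns)
  hfr <- matrix(0, N_CHANNELS, ns)
  for (k in seq_len(ns)) {
    i0 <- round(starts[k] * fs) + 1L
    i1 <- min(round((starts[k] + hp$segment_length_s) * fs), ncol(rec$signals))
    seg <- rec$signals[, i0:i1, drop = FALSE]
    seg_hf <- hf[, i0:i1, drop = FALSE]
    med <- apply(seg, 1, median)
    near[, k] <- 2 * apply(abs(seg - med), 1, quantile, probs = 0.99, names = FALSE)
    tot <- sqrt(rowMeans(seg^2))
    hfr[, k] <- ifelse(tot > 0, sqrt(rowMeans(seg_hf^2)) / tot, 1)
  }
  adm <- near >= hp$cl_amplitude_ratio_min * far_field_mv &
    hfr <= hp$quality_max_hf_ratio
  dimnames(adm) <- dimnames(near) <- dimnames(hfr) <-
    list(rec$channel_labels, NULL)
  structure(list(admissible = adm, near_field_mv = near,
                 far_field_mv = setNames(as.numeric(far_field_mv),
                                         rec$channel_labels),
                 hf_ratio = hfr),
            class = "quality_mask")
}
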