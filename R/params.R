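# Hyperparameter registry.  Every tunable of the mapping pipeline lives
# here so that the outcome-driven optimizer (and the config file) can see
# a single flat namespace.

.egf_param_defaults <- function() {
  list(
    # -- rasterization / optical flow --------------------------------------
    frame_rate_hz        = 50,     # frame rate of the interpolated image stack
    interp_grid          = 32L,    # refined grid size per axis (pixels)
    presmooth_sigma_ms   = 10,     # temporal Gaussian pre-smoothing (ms)
    presmooth_sigma_px   = 1,      # spatial Gaussian pre-smoothing (pixels)
    hs_alpha             = 1,      # Horn-Schunck smoothness weight
    hs_iterations        = 100L,   # Horn-Schunck Jacobi sweeps per frame pair
    # -- segmentation ------------------------------------------------------
    segment_length_s     = 2,      # analysis segment length (s)
    segment_stride_s     = 1,      # stride between overlapping segments (s)
    # -- singularity detection / tracking ----------------------------------
    singularity_radius   = 2,      # ring radius for radial/curl indices (grid units)
    ring_samples         = 16L,    # samples on the ring
    radial_index_min     = 0.85,   # source-ness cutoff on the ring radial index
    curl_rotational      = 0.7,    # |tangential index| >= this => rotational
    cluster_radius       = 1.5,    # track clustering radius (grid units)
    detection_window_s   = 0.5,    # sliding window for per-frame detection (s)
    detection_index_min  = 0.45,   # per-frame ring-index hit threshold
    # -- clinical thresholds -----------------------------------------------
    prevalence_dominant_pct  = 20,    # prevalence > this => dominant
    activity_significant_pct = 26.5,  # activity >= this => clinically significant
    # -- preprocessing -----------------------------------------------------
    highpass_hz          = 0.5,    # baseline-drift high-pass cutoff (Hz)
    qrst_pre_ms          = 100,    # QRST template window before R event (ms)
    qrst_post_ms         = 400,    # QRST template window after R event (ms)
    qrst_refractory_ms   = 200,    # minimum spacing between R events (ms)
    qrst_detect_mad      = 5,      # R detection threshold (robust SDs of median trace)
    qrst_min_amp_mv      = 0.1,    # absolute R-peak amplitude floor (mV)
    qrst_min_events      = 3L,     # below this the QRST template is unreliable
    # -- electrode quality -------------------------------------------------
    quality_hf_cutoff_hz = 100,    # high-frequency band start for the noise ratio
    quality_max_hf_ratio = 0.5,    # max fraction of RMS allowed above the cutoff
    cl_amplitude_ratio_min = 0.7,  # near-field/far-field amplitude admissibility
    # -- cycle length ------------------------------------------------------
    cl_bandpass_low_hz   = 40,     # activation band for the CL envelope (Hz)
    cl_bandpass_high_hz  = 250,
    cl_envelope_lowpass_hz = 20,   # envelope smoothing cutoff (Hz)
    cl_min_ms            = 100,    # CL search band (ms)
    cl_max_ms            = 350,
    cl_autocorr_min      = 0.6,    # autocorrelation peak admissibility
    cl_peak_tolerance    = 0.05,   # near-tie margin for harmonic resolution
    cl_window_s          = 4,      # autocorrelation window centred on each segment (s)
    cl_min_electrodes    = 8L,     # minimum admissible electrodes for segment stats
    entrain_on_threshold = 0.5,    # segment detection fraction labelling a segment ON
    # -- reproducibility ---------------------------------------------------
    rng_seed             = 1L
  )
}

#' Mapping pipeline hyperparameters
#'
#' Builds the registry of all named tunable knobs of the pipeline, with
#' defaults. Pass name = value pairs to override; unknown names are
#' rejected.
#'
#' @param ... Named overrides of individual hyperparameters.
#' @return An object of class `egf_params` (a named list).
#' @examples
#' hp <- egf_params(hs_alpha = 2, frame_rate_hz = 25)
#' @export
egf_params <- function(...) {
  p <- .egf_param_defaults()
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      stop("hyperparameter overrides must be named")
    }
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      stop("unknown hyperparameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  validate_egf_params(structure(p, class = "egf_params"))
}

#' @export
print.egf_params <- function(x, ...) {
  cat("<egf_params> ", length(unclass(x)), " knobs\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

validate_egf_params <- function(p) {
  num_pos <- c("frame_rate_hz", "interp_grid", "hs_alpha", "hs_iterations",
               "segment_length_s", "segment_stride_s", "singularity_radius",
               "ring_samples", "cluster_radius", "detection_window_s",
               "highpass_hz", "qrst_refractory_ms", "cl_min_ms", "cl_max_ms",
               "cl_window_s")
  for (nm in num_pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("hyperparameter ", nm, " must be a positive number")
    }
  }
  if (p$cl_max_ms <= p$cl_min_ms) stop("cl_max_ms must exceed cl_min_ms")
  if (p$segment_stride_s > p$segment_length_s) {
    stop("segment_stride_s must not exceed segment_length_s (segments overlap)")
  }
  if (p$interp_grid < 8) stop("interp_grid must be at least 8")
  p
}

#' Write hyperparameters to a YAML config file
#'
#' @param params An `egf_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_egf_params <- function(params, path) {
  stopifnot(inherits(params, "egf_params"))
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}

#' Read hyperparameters from a YAML config file
#'
#' Unknown keys in the file are rejected; missing keys fall back to the
#' defaults.
#'
#' @param path Config file path.
#' @return An `egf_params` object.
#' @export
read_egf_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(egf_params, raw)
}
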