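# End-to-end mapping pipeline: raw recording -> cleaned signals -> frames
# -> flow -> singularities -> tracks -> summary map.

#' Map a basket recording
#'
#' Runs the full pipeline: baseline-drift high-pass, ventricular event
#' detection, QRST template subtraction, quality assessment, robust
#' channel normalization, frame rasterization, Horn-Schunck flow,
#' segment averaging, singularity scan, track clustering, per-frame
#' detection refinement, activity computation, and classification.
#'
#' @param rec A raw `basket_recording`.
#' @param hp Hyperparameters.
#' @param meta Extra metadata stored in the summary map (e.g.
#'   `patient_id`, `atrium`).
#' @return An object of class `egf_map`: `map` (the [summary_map()]),
#'   `tracks`, `singularities`, `quality`, `flow`, `segments`,
#'   `recording` (the QRST-subtracted recording, for CL analysis),
#'   `events`, `n_segments`, `hp`.
#' @export
egf_map <- function(rec, hp = egf_params(), meta = list()) {
  stopifnot(inherits(rec, "basket_recording"))
  hpz <- highpass_detrend(rec, hp$highpass_hz)
  ev <- detect_ventricular_events(hpz, hp)
  sub <- subtract_qrst(hpz, ev, hp)
  qual <- assess_quality(sub$recording, sub$far_field_mv, hp)
  norm <- normalize_channels(sub$recording)
  frames <- build_frames(norm, qual, hp)
  flow <- flow_sequence(frames, hp)
  segs <- segment_flows(flow, hp)
  ns <- length(segs)
  sing <- do.call(rbind, lapply(segs, singularity_scan, hp = hp))
  tracks <- cluster_tracks(sing, ns, hp)
  tracks <- lapply(tracks, classify_and_flag, hp = hp)
  tracks <- refine_detection(tracks, flow, hp)
  tracks <- lapply(tracks, function(tr) {
    tr$activity_pct <- activity_of_track(tr, qual, hp)
    classify_and_flag(tr, hp)
  })
  # leading track first: by prevalence, then activity (deterministic)
  if (length(tracks) > 1L) {
    ord <- order(-vapply(tracks, `[[`, 0, "prevalence_pct"),
                 -vapply(tracks, `[[`, 0, "activity_pct"))
    tracks <- tracks[ord]
  }
  map <- summary_map(tracks, sing, ns, hp, meta = c(rec$meta, meta))
  structure(list(map = map, tracks = tracks, singularities = sing,
                 quality = qual, flow = flow, segments = segs,
                 recording = sub$recording, events = ev,
                 n_segments = ns, hp = hp),
            class = "egf_map")
}

#' @export
print.egf_map <- function(x, ...) {
  cat(sprintf("<egf_map> %d segments, %d tracks\n", x$n_segments,
              length(x$tracks)))
  for (tr in x$tracks) print(tr)
  invisible(x)
}

#' Cycle-length entrainment analysis of a mapped recording
#'
#' Computes per-segment spatial CL statistics on the QRST-subtracted
#' signals and contrasts them between ON and OFF segments of a track
#' (by default the leading track).
#'
#' @param mapped An [egf_map()] result.
#' @param track_id Track to contrast (default: the leading track).
#' @param hp Hyperparameters (defaults to those used for mapping).
#' @return A list `cl_stats` (from [spatial_cl_stats()]) and
#'   `entrainment` (from [entrainment_contrast()], possibly `NULL`).
#' @export
egf_entrainment <- function(mapped, track_id = NULL, hp = NULL) {
  stopifnot(inherits(mapped, "egf_map"))
  hp <- hp %||% mapped$hp
  cl <- spatial_cl_stats(mapped$recording, mapped$quality, hp)
  if (!length(mapped$tracks)) return(list(cl_stats = cl, entrainment = NULL))
  tr <- if (is.null(track_id)) {
    mapped$tracks[[1]]
  } else {
    mapped$tracks[[which(vapply(mapped$tracks, `[[`, 0L, "id") == track_id)[1]]]
  }
  list(cl_stats = cl,
       entrainment = entrainment_contrast(cl, tr, hp$entrain_on_threshold))
}
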