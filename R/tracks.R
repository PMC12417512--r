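# Source tracks: clustering of per-segment singularities into persistent
# sources with prevalence, per-segment detection, quality-adjusted
# activity, and classification against the clinical thresholds.

.new_track <- function(id) {
  list(id = id, members = list(), segments = integer(0),
       centroid = c(s = NA_real_, e = NA_real_))
}

#' Cluster per-segment singularities into source tracks
#'
#' Greedy centroid clustering on the periodic grid: walking segments in
#' order (and singularities in their deterministic scan order), each
#' singularity joins the nearest existing track whose centroid is within
#' `cluster_radius` grid units, otherwise it seeds a new track. Centroids
#' are circular means on the spline axis. Per-segment detection defaults
#' to binary membership; [refine_detection()] replaces it with the
#' per-frame hit fraction when the full flow sequence is available.
#'
#' @param singularities A data.frame of singularities from
#'   [singularity_scan()] over all segments (rows in segment order).
#' @param n_segments Total number of segments in the recording.
#' @param hp Hyperparameters.
#' @return A list of `source_track` objects with fields `id`, `centroid`,
#'   `members` (data.frame), `segments`, `prevalence_pct`,
#'   `segment_detection` (length `n_segments`), `type`,
#'   `mean_abs_tangential`, and placeholder flags.
#' @export
cluster_tracks <- function(singularities, n_segments, hp = egf_params()) {
  tracks <- list()
  if (nrow(singularities)) {
    singularities <- singularities[order(singularities$segment_index), ,
                                   drop = FALSE]
    for (r in seq_len(nrow(singularities))) {
      p <- c(s = singularities$s[r], e = singularities$e[r])
      if (length(tracks)) {
        cent <- do.call(rbind, lapply(tracks, `[[`, "centroid"))
        d <- grid_distance(cent, matrix(p, nrow(cent), 2, byrow = TRUE))
        j <- which.min(d)
      }
      if (!length(tracks) || d[j] > hp$cluster_radius) {
        tracks[[length(tracks) + 1L]] <- .new_track(length(tracks) + 1L)
        j <- length(tracks)
      }
      tr <- tracks[[j]]
      tr$members[[length(tr$members) + 1L]] <- singularities[r, , drop = FALSE]
      tr$segments <- union(tr$segments, singularities$segment_index[r])
      mem <- do.call(rbind, tr$members)
      tr$centroid <- grid_centroid(as.matrix(mem[, c("s", "e")]))
      tracks[[j]] <- tr
    }
  }
  lapply(tracks, function(tr) {
    mem <- do.call(rbind, tr$members)
    det <- as.numeric(seq_len(n_segments) %in% tr$segments)
    structure(list(
      id = tr$id,
      centroid = tr$centroid,
      members = mem,
      segments = sort(tr$segments),
      n_segments = n_segments,
      prevalence_pct = 100 * length(tr$segments) / n_segments,
      segment_detection = det,
      mean_abs_tangential = mean(abs(mem$tangential_index)),
      mean_radial = mean(mem$radial_index),
      type = NA_character_, activity_pct = NA_real_,
      dominant = NA, significant = NA
    ), class = "source_track")
  })
}

#' @export
print.source_track <- function(x, ...) {
  cat(sprintf(paste0("<source_track #%d> %s at (%.2f, %.2f): prevalence ",
                     "%.1f%%, activity %s%%%s%s\n"),
              x$id, ifelse(is.na(x$type), "?", x$type),
              x$centroid[["s"]], x$centroid[["e"]], x$prevalence_pct,
              ifelse(is.na(x$activity_pct), "?",
                     sprintf("%.1f", x$activity_pct)),
              ifelse(isTRUE(x$dominant), ", dominant", ""),
              ifelse(isTRUE(x$significant), ", significant", "")))
  invisible(x)
}

#' Refine per-segment detection from per-frame ring indices
#'
#' For each track, the ring index matched to its type (radial for focal,
#' absolute tangential for rotational) is evaluated at the track centroid
#' on a sliding `detection_window_s` mean of the frame-pair flow fields.
#' A frame counts as a hit when the index reaches
#' `detection_index_min`; each segment's detection becomes the hit
#' fraction of its frames.
#'
#' @param tracks Tracks from [cluster_tracks()].
#' @param flow The full [flow_sequence()].
#' @param hp Hyperparameters.
#' @return The tracks with `segment_detection` updated.
#' @export
refine_detection <- function(tracks, flow, hp = egf_params()) {
  if (!length(tracks)) return(tracks)
  G <- flow$grid
  m <- as.integer(hp$ring_samples)
  phi <- 2 * pi * (seq_len(m) - 1) / m
  nfl <- ncol(flow$u)
  half <- max(0L, round(hp$detection_window_s * flow$frame_rate_hz / 2))
  win <- 2L * half + 1L
  starts <- segment_starts(flow$duration_s, hp)
  ns <- n_segments_for(flow$duration_s, hp)
  sc <- pixel_scale(G)
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    W <- .bilinear_weights_pixels(
      tr$centroid[["s"]] + hp$singularity_radius * cos(phi),
      tr$centroid[["e"]] + hp$singularity_radius * sin(phi), G)
    us <- as.matrix(W %*% flow$u) * sc[["s"]]   # m x nfl, grid units
    vs <- as.matrix(W %*% flow$v) * sc[["e"]]
    # sliding-window mean over frames
    if (win > 1L) {
      k <- rep(1 / win, win)
      us <- t(apply(cbind(us[, rep(1L, half)], us, us[, rep(nfl, half)]), 1,
                    function(z) stats::filter(z, k, sides = 2)))[, (half + 1):(half + nfl)]
      vs <- t(apply(cbind(vs[, rep(1L, half)], vs, vs[, rep(nfl, half)]), 1,
                    function(z) stats::filter(z, k, sides = 2)))[, (half + 1):(half + nfl)]
    }
    nrm <- sqrt(us^2 + vs^2)
    ok <- nrm > 1e-9
    nu <- ifelse(ok, us / nrm, 0); nv <- ifelse(ok, vs / nrm, 0)
    radial <- colMeans(nu * cos(phi) + nv * sin(phi))
    tangential <- colMeans(-nu * sin(phi) + nv * cos(phi))
    use_curl <- !is.na(tr$type) && identical(tr$type, "rotational") ||
      (is.na(tr$type) && tr$mean_abs_tangential >= hp$curl_rotational)
    idx <- if (use_curl) abs(tangential) else radial
    hit <- idx >= hp$detection_index_min
    det <- vapply(seq_len(ns), function(kseg) {
      sel <- flow$times_s >= starts[kseg] &
        flow$times_s < starts[kseg] + hp$segment_length_s
      mean(hit[sel])
    }, 0)
    tr$segment_detection <- det
    tracks[[ti]] <- tr
  }
  tracks
}

#' Quality-adjusted activity of a source track
#'
#' Activity is the quality-weighted mean per-segment detection, in
#' percent: `100 * sum(w_s d_s) / sum(w_s)` where `d_s` is the segment
#' detection fraction and the binary weight `w_s` marks segments in which
#' the electrodes within `cluster_radius` of the track centroid are
#' majority quality-admissible. Returns 0 when no segment is admissible.
#' With all segments admissible and binary detection, activity equals
#' prevalence.
#'
#' @param track A `source_track`.
#' @param quality A [assess_quality()] mask, or `NULL` for all-admissible.
#' @param hp Hyperparameters.
#' @return Activity percentage in `[0, 100]`.
#' @export
activity_of_track <- function(track, quality = NULL, hp = egf_params()) {
  if (is.null(track$members) || !nrow(track$members)) stop("empty track")
  d <- track$segment_detection
  ns <- length(d)
  if (is.null(quality)) {
    w <- rep(1, ns)
  } else {
    epos <- electrode_grid_positions()
    near <- which(grid_distance(epos, matrix(track$centroid, nrow(epos), 2,
                                             byrow = TRUE)) <= hp$cluster_radius)
    if (!length(near)) near <- seq_len(N_CHANNELS)
    w <- as.numeric(colMeans(quality$admissible[near, seq_len(ns), drop = FALSE]) > 0.5)
  }
  if (sum(w) == 0) return(0)
  100 * sum(w * d) / sum(w)
}

#' Classify a track and set its clinical flags
#'
#' Type is rotational iff the mean absolute tangential index of the
#' member singularities is at least `curl_rotational`, else focal.
#' `dominant` iff prevalence strictly exceeds `prevalence_dominant_pct`;
#' `significant` iff activity is at least `activity_significant_pct`.
#'
#' @param track A `source_track` with prevalence/activity computed.
#' @param hp Hyperparameters.
#' @return The track with `type`, `dominant`, `significant` set.
#' @export
classify_and_flag <- function(track, hp = egf_params()) {
  track$type <- if (track$mean_abs_tangential >= hp$curl_rotational) {
    "rotational"
  } else "focal"
  track$dominant <- track$prevalence_pct > hp$prevalence_dominant_pct
  track$significant <- !is.na(track$activity_pct) &&
    track$activity_pct >= hp$activity_significant_pct
  track
}

#' Build the summary heat map of a recording
#'
#' Per-pixel heat is the fraction of segments in which a singularity lay
#' within `cluster_radius` of the pixel; heat therefore peaks at
#' persistent source locations at a height equal to their prevalence
#' fraction.
#'
#' @param tracks Classified tracks of the recording.
#' @param singularities All per-segment singularities (data.frame).
#' @param n_segments Segment count.
#' @param hp Hyperparameters.
#' @param meta Recording metadata to embed (e.g. patient id, atrium).
#' @return An object of class `summary_map`: `heat` (G x G in [0, 1]),
#'   `tracks`, `n_segments`, `meta`.
#' @export
summary_map <- function(tracks, singularities, n_segments,
                        hp = egf_params(), meta = list()) {
  G <- as.integer(hp$interp_grid)
  pc <- pixel_coords(G)
  px <- as.matrix(expand.grid(s = pc$s, e = pc$e))
  heat <- numeric(G * G)
  if (nrow(singularities) && n_segments > 0) {
    for (k in unique(singularities$segment_index)) {
      sk <- singularities[singularities$segment_index == k, , drop = FALSE]
      covered <- rep(FALSE, G * G)
      for (r in seq_len(nrow(sk))) {
        d <- grid_distance(px, matrix(c(sk$s[r], sk$e[r]), nrow(px), 2,
                                      byrow = TRUE))
        covered <- covered | d <= hp$cluster_radius
      }
      heat <- heat + covered
    }
    heat <- heat / n_segments
  }
  structure(list(heat = matrix(heat, G, G), tracks = tracks,
                 n_segments = n_segments, meta = meta),
            class = "summary_map")
}

#' @export
print.summary_map <- function(x, ...) {
  cat(sprintf("<summary_map> %d tracks over %d segments; max heat %.2f\n",
              length(x$tracks), x$n_segments, max(x$heat)))
  invisible(x)
}

#' Export a summary map's tracks as JSON
#'
#' @param map A `summary_map`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tracks_to_json <- function(map, path = NULL) {
  lst <- lapply(map$tracks, function(tr) list(
    id = tr$id,
    centroid = list(s = unname(tr$centroid[["s"]]), e = unname(tr$centroid[["e"]])),
    prevalence_pct = tr$prevalence_pct,
    activity_pct = tr$activity_pct,
    segment_detection = tr$segment_detection,
    type = tr$type, dominant = tr$dominant, significant = tr$significant))
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Cohort-level source summary
#'
#' Tallies sources across a cohort of summary maps (one per recording,
#' tagged with `patient_id` and `atrium` in their metadata): total source
#' count, dominant count, patients harboring a dominant source, mean
#' dominant sources per harboring patient (1 decimal), LA/RA split of
#' dominant sources, and the per-patient sub-dominant count mean and SD.
#'
#' @param maps List of `summary_map` objects.
#' @return A list of cohort summary statistics.
#' @export
cohort_stats <- function(maps) {
  stopifnot(length(maps) >= 1L)
  rows <- do.call(rbind, lapply(maps, function(m) {
    pid <- m$meta$patient_id %||% "?"
    atr <- m$meta$atrium %||% NA_character_
    if (!length(m$tracks)) {
      return(data.frame(patient_id = character(0), atrium = character(0),
                        dominant = logical(0)))
    }
    data.frame(patient_id = pid, atrium = atr,
               dominant = vapply(m$tracks, function(t) isTRUE(t$dominant), NA))
  }))
  n_sources <- nrow(rows)
  dom <- rows[rows$dominant, , drop = FALSE]
  per_pat_dom <- table(factor(dom$patient_id))
  harboring <- sum(per_pat_dom > 0)
  sub <- rows[!rows$dominant, , drop = FALSE]
  per_pat_sub <- table(factor(sub$patient_id))
  list(
    n_sources = n_sources,
    n_dominant = nrow(dom),
    pct_dominant = if (n_sources) 100 * nrow(dom) / n_sources else NA_real_,
    n_patients = length(unique(rows$patient_id)),
    n_patients_with_dominant = harboring,
    mean_dominant_per_harboring = if (harboring) {
      round(nrow(dom) / harboring, 1)
    } else NA_real_,
    dominant_by_atrium = if (nrow(dom)) table(factor(dom$atrium)) else NULL,
    subdominant_per_patient_mean = if (nrow(sub)) mean(per_pat_sub) else NA_real_,
    subdominant_per_patient_sd = if (nrow(sub)) sd(per_pat_sub) else NA_real_
  )
}
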