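# Optical-flow layer: Horn-Schunck velocity fields per frame pair and
# their aggregation over overlapping 2-second segments.
#
# Flow components are in pixels per frame on the same lattice as the
# frames: u along the spline axis (periodic), v along the electrode axis.

#' Horn-Schunck optical flow between two frames
#'
#' Classic Horn-Schunck (brightness constancy + quadratic smoothness,
#' Jacobi fixed-point iterations from zero flow) with boundary handling
#' matched to the basket topology: periodic on the spline axis,
#' replicate-clamped on the electrode axis. The frame pair is jointly
#' standardized first, so the flow is invariant to affine intensity
#' changes applied to both frames.
#'
#' @param frame_a,frame_b Numeric G x G matrices (rows = spline axis) or
#'   length-G^2 vectors.
#' @param alpha Smoothness weight (> 0).
#' @param n_iter Number of Jacobi sweeps (>= 1).
#' @return A list with `u`, `v` (G x G matrices, pixels/frame).
#' @export
horn_schunck <- function(frame_a, frame_b, alpha = 1, n_iter = 100) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b))) stop("frame mismatch: differing frame shapes")
  if (nrow(a) != ncol(a)) stop("frame mismatch: frames must be square")
  G <- nrow(a)
  res <- .hs_flow_cpp(cbind(as.vector(a), as.vector(b)), G, alpha,
                      as.integer(n_iter))
  list(u = matrix(res$u[, 1], G, G), v = matrix(res$v[, 1], G, G))
}

#' Flow fields for every consecutive frame pair
#'
#' @param frames A [build_frames()] `frame_sequence`.
#' @param hp Hyperparameters (`hs_alpha`, `hs_iterations`).
#' @return An object of class `flow_sequence`: `u`, `v` (G^2 x (n_frames
#'   - 1) matrices, one column per frame pair), `grid`, `frame_rate_hz`,
#'   `duration_s`, and `times_s` (mid-pair timestamps).
#' @export
flow_sequence <- function(frames, hp = egf_params()) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (ncol(frames$frames) < 2L) stop("too short: need at least 2 frames")
  res <- .hs_flow_cpp(frames$frames, frames$grid, hp$hs_alpha,
                      as.integer(hp$hs_iterations))
  structure(list(u = res$u, v = res$v, grid = frames$grid,
                 frame_rate_hz = frames$frame_rate_hz,
                 duration_s = frames$duration_s,
                 times_s = (seq_len(ncol(res$u)) - 0.5) / frames$frame_rate_hz),
            class = "flow_sequence")
}

#' @export
print.flow_sequence <- function(x, ...) {
  cat(sprintf("<flow_sequence> %d fields of %dx%d @ %g Hz\n",
              ncol(x$u), x$grid, x$grid, x$frame_rate_hz))
  invisible(x)
}

#' Average flow over overlapping analysis segments
#'
#' Frame-pair flow fields are vector-averaged over each
#' `[t, t + segment_length_s)` window advanced by `segment_stride_s`;
#' trailing incomplete windows are dropped (60 s at the defaults gives 59
#' segments).
#'
#' @param flow A [flow_sequence()].
#' @param hp Hyperparameters.
#' @return A list of `segment_flow` objects with fields `segment_index`,
#'   `t_start_s`, `t_end_s`, `u`, `v` (G x G mean fields), `n_frames`.
#' @export
segment_flows <- function(flow, hp = egf_params()) {
  stopifnot(inherits(flow, "flow_sequence"))
  ns <- n_segments_for(flow$duration_s, hp)
  if (ns < 1L) stop("too short: recording shorter than one segment")
  G <- flow$grid
  starts <- segment_starts(flow$duration_s, hp)
  lapply(seq_len(ns), function(k) {
    sel <- flow$times_s >= starts[k] &
      flow$times_s < starts[k] + hp$segment_length_s
    structure(list(
      segment_index = k,
      t_start_s = starts[k],
      t_end_s = starts[k] + hp$segment_length_s,
      u = matrix(rowMeans(flow$u[, sel, drop = FALSE]), G, G),
      v = matrix(rowMeans(flow$v[, sel, drop = FALSE]), G, G),
      n_frames = sum(sel)
    ), class = "segment_flow")
  })
}
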