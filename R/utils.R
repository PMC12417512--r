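# Shared helpers.

#' Number of overlapping analysis segments in a recording
#'
#' `floor((duration - segment_length) / stride) + 1`; a 60 s recording at
#' the default 2 s length / 1 s stride gives 59 segments.
#'
#' @param duration_s Recording duration (s).
#' @param hp Hyperparameters.
#' @return Integer segment count (0 if the recording is shorter than one
#'   segment).
#' @export
n_segments_for <- function(duration_s, hp = egf_params()) {
  ns <- floor((duration_s - hp$segment_length_s) / hp$segment_stride_s + 1e-9) + 1
  max(0L, as.integer(ns))
}

# Start times (s) of the analysis segments.
segment_starts <- function(duration_s, hp) {
  (seq_len(n_segments_for(duration_s, hp)) - 1) * hp$segment_stride_s
}

# Segment index covering time t (clamped); used to pick the quality-mask
# column for a frame.
segment_index_at <- function(t, duration_s, hp) {
  ns <- n_segments_for(duration_s, hp)
  pmin(pmax(floor(t / hp$segment_stride_s) + 1, 1), ns)
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}
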