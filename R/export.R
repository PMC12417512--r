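# Delimited exports of intermediate products (flow segments, quality
# masks, CL tables) for inspection outside R.

#' Export a segment's mean flow as paired delimited matrices
#'
#' Writes `segment_<k>_u.tsv` and `segment_<k>_v.tsv` (G x G, rows =
#' spline axis) into `dir`.
#'
#' @param seg A `segment_flow` from [segment_flows()].
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_segment_flow <- function(seg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("segment_%03d_%s.tsv", seg$segment_index,
                                  c("u", "v")))
  utils::write.table(seg$u, paths[1], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(seg$v, paths[2], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}

#' Export a quality mask as a delimited matrix
#'
#' One row per electrode (labelled), one column per segment; entries are
#' 0/1 admissibility.
#'
#' @param quality A [assess_quality()] mask.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quality_mask <- function(quality, path) {
  stopifnot(inherits(quality, "quality_mask"))
  dt <- data.frame(channel = rownames(quality$admissible),
                   quality$admissible + 0L, check.names = FALSE)
  names(dt)[-1] <- paste0("seg", seq_len(ncol(quality$admissible)))
  utils::write.table(dt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
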