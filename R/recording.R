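# BasketRecording: 64-channel unipolar voltage matrix plus metadata.

#' Construct a basket recording
#'
#' @param signals Numeric 64 x n matrix of unipolar voltages (millivolts),
#'   one row per channel.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param channel_labels Labels for the rows of `signals`; must be a
#'   permutation of "A1".."H8". Rows are reordered to canonical order.
#' @param meta Free-form named list of annotations (e.g. `atrium`,
#'   `recording_id`).
#' @return An object of class `basket_recording` with fields `signals`
#'   (canonical channel order), `sample_rate`, `channel_labels`,
#'   `duration_s`, `meta`.
#' @export
basket_recording <- function(signals, sample_rate = 1000,
                             channel_labels = basket_channel_labels(),
                             meta = list()) {
  signals <- as.matrix(signals)
  canon <- basket_channel_labels()
  if (nrow(signals) != N_CHANNELS) {
    stop("malformed recording: expected 64 channels, got ", nrow(signals))
  }
  if (length(channel_labels) != N_CHANNELS) {
    stop("malformed recording: expected 64 channel labels")
  }
  bad <- setdiff(channel_labels, canon)
  if (length(bad)) stop("bad channel label: ", paste(bad, collapse = ", "))
  if (anyDuplicated(channel_labels)) {
    stop("malformed recording: duplicated channel labels")
  }
  if (!all(is.finite(signals))) stop("corrupt data: non-finite samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("bad sample rate")
  # normalize row order to A1..H8
  signals <- signals[match(canon, channel_labels), , drop = FALSE]
  rownames(signals) <- canon
  structure(list(
    signals = signals,
    sample_rate = sample_rate,
    channel_labels = canon,
    duration_s = ncol(signals) / sample_rate,
    meta = meta
  ), class = "basket_recording")
}

#' @export
print.basket_recording <- function(x, ...) {
  cat(sprintf("<basket_recording> 64 x %d samples, %.3f s @ %g Hz\n",
              ncol(x$signals), x$duration_s, x$sample_rate))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a basket recording to disk
#'
#' Two interchange formats are supported:
#' \describe{
#'   \item{`"delimited"`}{Tab-separated text: a one-line header comment
#'     carrying sample rate and JSON metadata, then one row per channel
#'     with the label in the first column.}
#'   \item{`"binary"`}{A serialized R container (RDS) holding the signal
#'     array and a small metadata block; round-trips bit-exactly.}
#' }
#'
#' @param rec A `basket_recording`.
#' @param path Output path.
#' @param format `"delimited"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "basket_recording"))
  if (format == "binary") {
    saveRDS(list(egflow_recording = 1L,
                 signals = rec$signals,
                 sample_rate = rec$sample_rate,
                 channel_labels = rec$channel_labels,
                 meta = rec$meta), path)
  } else {
    hdr <- sprintf("# egflow-recording sample_rate_hz=%s meta=%s",
                   format(rec$sample_rate, digits = 15),
                   jsonlite::toJSON(rec$meta, auto_unbox = TRUE))
    writeLines(hdr, path)
    dt <- data.table::data.table(channel = rec$channel_labels)
    dt <- cbind(dt, data.table::as.data.table(rec$signals))
    data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a basket recording from disk
#'
#' Channel order is normalized to A1..H8 regardless of on-disk order.
#'
#' @param path Input path.
#' @param format `"delimited"` or `"binary"` (must match the file content).
#' @return A `basket_recording`.
#' @export
read_recording <- function(path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "binary") {
    obj <- tryCatch(readRDS(path), error = function(e) {
      stop("malformed recording: not a binary recording container")
    })
    if (!is.list(obj) || is.null(obj$egflow_recording)) {
      stop("malformed recording: not a binary recording container")
    }
    return(basket_recording(obj$signals, obj$sample_rate,
                            obj$channel_labels, obj$meta))
  }
  hdr <- readLines(path, n = 1L)
  sample_rate <- 1000
  meta <- list()
  if (startsWith(hdr, "# egflow-recording")) {
    m <- regmatches(hdr, regexec("sample_rate_hz=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2L) sample_rate <- as.numeric(m[2])
    mj <- sub(".*meta=", "", hdr)
    meta <- tryCatch(as.list(jsonlite::fromJSON(mj)), error = function(e) list())
    skip <- 1L
  } else {
    skip <- 0L
  }
  dt <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE)
  if (!"channel" %in% names(dt)) {
    stop("malformed recording: missing channel column")
  }
  labels <- as.character(dt$channel)
  sig <- as.matrix(dt[, setdiff(names(dt), "channel"), with = FALSE])
  storage.mode(sig) <- "double"
  dimnames(sig) <- NULL
  basket_recording(sig, sample_rate, labels, meta)
}
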