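#' EEG recordings
#'
#' An `eeg_recording` is a samples-by-channels numeric matrix (microvolts)
#' together with its sampling rate, a channel layout, and bad-segment
#' annotations. It is the container every signal-processing and microstate
#' operation works on.
#'
#' @param data Numeric matrix, samples x channels.
#' @param sfreq Sampling rate in Hz.
#' @param layout An [channel_layout()] whose names match `colnames(data)`
#'   (created from generic names when omitted).
#' @param annotations Tibble with columns `onset_s`, `duration_s`, `label`
#'   marking bad segments.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, layout = NULL, annotations = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  rownames(data) <- NULL
  if (!is_scalar_number(sfreq) || sfreq <= 0)
    stop_msnf("sfreq must be a positive number", "recording")
  if (is.null(layout)) {
    nm <- colnames(data) %||% paste0("E", seq_len(ncol(data)))
    pos <- fibonacci_cap(ncol(data))
    layout <- channel_layout(nm, pos)
  }
  if (ncol(data) != length(layout$names))
    stop_msnf("data has a different channel count than the layout", "recording")
  colnames(data) <- layout$names
  annotations <- annotations %||%
    tibble::tibble(onset_s = numeric(), duration_s = numeric(), label = character())
  structure(
    list(data = data, sfreq = sfreq, layout = layout, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$sfreq, nrow(x$data) / x$sfreq))
  if (length(x$layout$bads))
    cat("  bads:", paste(x$layout$bads, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    t = rep((seq_len(nrow(x$data)) - 1) / x$sfreq, ncol(x$data)),
    channel = rep(colnames(x$data), each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

# subset samples (half-open 0-based [start, end) in samples)
crop_samples <- function(x, start, end) {
  stopifnot(start >= 0, end <= nrow(x$data), end > start)
  eeg_recording(x$data[(start + 1):end, , drop = FALSE], x$sfreq, x$layout)
}

#' Drop channels by name
#'
#' @param recording An `eeg_recording`.
#' @param channels Channel names to drop; names absent from the layout are
#'   ignored, so dropping mastoids from a mastoid-free cap is a no-op.
#' @return An `eeg_recording` without those channels.
#' @export
drop_channels <- function(recording, channels) {
  keep <- !(recording$layout$names %in% channels)
  if (all(keep)) return(recording)
  lay <- channel_layout(
    recording$layout$names[keep],
    recording$layout$positions[keep, , drop = FALSE],
    bads = setdiff(recording$layout$bads, channels)
  )
  eeg_recording(recording$data[, keep, drop = FALSE], recording$sfreq, lay,
                recording$annotations)
}

#' Read and write recordings as delimited text
#'
#' Recordings are serialized as a tab-separated matrix (channel-name header,
#' one row per sample, microvolts) plus a JSON sidecar `<path>.json` carrying
#' the sampling rate, channel positions, and bad channels.
#'
#' @param recording An `eeg_recording`.
#' @param path Path of the `.tsv` file to write/read.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  utils::write.table(recording$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(
    sfreq = recording$sfreq,
    names = recording$layout$names,
    positions = unname(apply(recording$layout$positions, 1, as.numeric,
                             simplify = FALSE)),
    bads = recording$layout$bads
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  data <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pos <- meta$positions
  if (!is.matrix(pos)) pos <- do.call(rbind, lapply(pos, as.numeric))
  lay <- channel_layout(meta$names, pos, bads = meta$bads %||% character())
  eeg_recording(data, meta$sfreq, lay)
}
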