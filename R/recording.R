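#' Multichannel EEG recording
#'
#' Container for a channels-by-samples potential matrix (microvolts) with its
#' sampling rate, channel names, optional unit-sphere sensor positions and
#' reference state.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param positions Optional n x 3 matrix of unit-norm sensor positions.
#' @param reference One of `"other"`, `"mastoid"`, `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          reference = c("other", "mastoid", "average")) {
  data <- as.matrix(data)
  reference <- match.arg(reference)
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the number of channels")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3)
      stop("positions must be an n_channels x 3 matrix")
    nrm <- sqrt(rowSums(positions^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("positions must be unit-norm (on the unit sphere)")
  }
  dimnames(data) <- list(channel_names, NULL)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 positions = positions, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so each
#' column of the potential matrix sums to zero.
#'
#' @param rec An [eeg_recording()].
#' @return The average-referenced recording.
#' @export
average_reference <- function(rec) {
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Write a recording as CSV plus JSON sidecar
#'
#' The data matrix is written samples-by-channels as a plain CSV with a header
#' row of channel names; sampling rate, channel names, positions and reference
#' go to `<path>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param path Path of the CSV file to create (sidecar adds `.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(apply(t(rec$data), 2, sprintf, fmt = "%.17g"))
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(fs = rec$fs, channel_names = rec$channel_names,
               reference = rec$reference)
  if (!is.null(rec$positions))
    side$positions <- unname(apply(rec$positions, 1, as.numeric,
                                   simplify = FALSE))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording
#'
#' Reads the CSV + JSON-sidecar format written by [write_recording()]. The
#' binary clinical formats (BDF/EDF/FIF) are not parsed by this package;
#' convert such files to the CSV + sidecar layout first.
#'
#' @param path Path to the CSV file (expects `<path>.json` next to it).
#' @param format Only `"csv"` is supported.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf", "bdf", "fif")) {
  format <- match.arg(format)
  if (format != "csv")
    stop("format '", format, "' is not supported; supply CSV + JSON sidecar")
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) != length(side$channel_names))
    stop("malformed recording file (channel count mismatch): ", path)
  pos <- side$positions
  if (!is.null(pos) && !is.matrix(pos))
    pos <- do.call(rbind, lapply(pos, as.numeric))
  eeg_recording(t(as.matrix(df)), fs = side$fs,
                channel_names = side$channel_names, positions = pos,
                reference = side$reference %||% "other")
}
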