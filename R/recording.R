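#' Multichannel recording container
#'
#' A `recording` wraps a channels x samples numeric matrix together with its
#' sampling rate and channel labels. It is the common carrier for EEG- and
#' LFP-style data throughout the package.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz, a single positive number.
#' @param channel_labels optional character vector of channel names; defaults
#'   to `ch1..chK`.
#' @param units signal units recorded in metadata (default `"uV"`).
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100)
#' nchannels(rec); nsamples(rec)
#' @export
recording <- function(data, fs, channel_labels = NULL, units = "uV") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (nrow(data) < 1 || ncol(data) < 2)
    stop("recording needs at least 1 channel and 2 samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match channel count")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 units = units),
            class = "recording")
}

#' @rdname recording
#' @param x a `recording`.
#' @export
nchannels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
nsamples <- function(x) ncol(x$data)

#' @rdname recording
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.2f s, %s)\n",
              nchannels(x), nsamples(x), x$fs, duration(x), x$units))
  invisible(x)
}

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The on-disk format is a comma-delimited matrix with one row per channel and
#' no header, plus `<path>.json` holding `{fs, channel_labels, units}`.
#'
#' @param rec a `recording`.
#' @param path file path for the matrix; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels, units = rec$units),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  recording(m, fs = meta$fs, channel_labels = meta$channel_labels,
            units = if (is.null(meta$units)) "uV" else meta$units)
}

#' Epoched (stimulus-locked) data container
#'
#' Holds a channels x samples x epochs array with a shared time axis relative
#' to the stimulus at t = 0.
#'
#' @param data numeric array, channels x samples x epochs.
#' @param fs sampling rate in Hz.
#' @param t0_index sample index (1-based) corresponding to t = 0.
#' @param channel_labels optional channel names.
#' @return An object of class `epochs` with a `time` axis in seconds.
#' @export
epochs <- function(data, fs, t0_index, channel_labels = NULL) {
  if (length(dim(data)) != 3) stop("`data` must be a 3-d array (ch x samp x epoch)")
  if (t0_index < 1 || t0_index > dim(data)[2]) stop("t0_index outside the epoch")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[1]))
  time <- (seq_len(dim(data)[2]) - t0_index) / fs
  structure(list(data = data, fs = fs, time = time,
                 channel_labels = channel_labels),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d channel(s) x %d samples x %d epochs @ %g Hz, t in [%.3f, %.3f] s\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time)))
  invisible(x)
}

# ---- minimal EDF support (convenience path; 16-bit integer records) --------

#' Read or write a recording in EDF format
#'
#' Minimal European Data Format support: a standard 256-byte header per file
#' and per signal, all signals at one sampling rate, 16-bit little-endian
#' samples. Intended as a convenience ingestion path; the delimited-text
#' format of [write_recording()] is the package's primary interchange format.
#'
#' @param path file path.
#' @param rec a `recording` (for `write_edf`).
#' @param record_duration EDF data-record length in seconds.
#' @return `read_edf` returns a `recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)  # version, patient, recording, date, time
  hdr(8)                                    # header bytes
  hdr(44)
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labels <- vapply(seq_len(ns), function(i) hdr(16), "")
  for (i in seq_len(ns)) hdr(80)            # transducer
  units <- vapply(seq_len(ns), function(i) hdr(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  for (i in seq_len(ns)) hdr(80)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) hdr(8), ""))
  for (i in seq_len(ns)) hdr(32)            # reserved
  if (length(unique(spr)) != 1)
    stop("read_edf supports a single sampling rate across signals")
  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[s], size = 2, endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- pmin[s] + gain[s] * (dig - dmin[s])
    }
  }
  recording(out, fs = spr[1] / rec_dur, channel_labels = labels,
            units = units[1])
}

#' @rdname read_edf
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  stopifnot(inherits(rec, "recording"))
  spr <- as.integer(round(rec$fs * record_duration))
  n_rec <- floor(nsamples(rec) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  ns <- nchannels(rec)
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmin <- apply(x, 1, min) - 1e-9; pmax <- apply(x, 1, max) + 1e-9
  dmin <- rep(-32768, ns); dmax <- rep(32767, ns)
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(format(s), 1, n)
    writeBin(charToRaw(formatC(s, width = -n)), con)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44); pad(n_rec, 8)
  pad(format(record_duration), 8); pad(ns, 4)
  for (s in rec$channel_labels) pad(s, 16)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(rec$units, 8)
  for (i in 1:ns) pad(format(pmin[i], digits = 6), 8)
  for (i in 1:ns) pad(format(pmax[i], digits = 6), 8)
  for (i in 1:ns) pad(dmin[i], 8)
  for (i in 1:ns) pad(dmax[i], 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(spr, 8)
  for (i in 1:ns) pad("", 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) for (s in seq_len(ns)) {
    dig <- as.integer(round((x[s, ((r - 1) * spr + 1):(r * spr)] - pmin[s]) / gain[s] + dmin[s]))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}
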