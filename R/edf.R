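#' Minimal EDF/EDF+ reader and writer
#'
#' European Data Format stores a fixed 256-byte ASCII header, one 256-byte
#' header block per signal, then interleaved data records of 16-bit
#' little-endian two's-complement samples.  Physical values are recovered by
#' the per-signal linear map from the digital to the physical range.  Only
#' the subset needed for continuous multichannel EEG is implemented: equal
#' sampling rate across signals, uninterrupted records, physical dimension
#' microvolts.
#'
#' @param path file path.
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz (samples per second, one data record = 1 s).
#' @param channel_labels character vector, one per column of `data`.
#' @param start_datetime POSIXct used to fill the header date fields.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns a list
#'   with `data` (matrix, microvolts), `fs`, `channel_labels`.
#' @export
write_edf <- function(path, data, fs, channel_labels,
                      start_datetime = as.POSIXct("2000-01-01 00:00:00",
                                                  tz = "UTC")) {
  data <- as.matrix(data)
  ns <- ncol(data)
  stopifnot(length(channel_labels) == ns, fs > 0)
  spr <- as.integer(round(fs))              # samples per 1-s record
  n_rec <- floor(nrow(data) / spr)
  if (n_rec < 1) stop("record shorter than one EDF data record (1 s)")
  data <- data[seq_len(n_rec * spr), , drop = FALSE]

  # physical range: symmetric, covering the data with headroom
  pmax_ <- max(abs(data), 1e-6) * 1.001
  dig_min <- -32768L; dig_max <- 32767L

  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad("X X X X", 80),                         # patient id (EDF+ minimal)
    pad("Startdate X X X X", 80),               # recording id
    format(start_datetime, "%d.%m.%y"),
    format(start_datetime, "%H.%M.%S"),
    pad(256 * (1 + ns), 8),
    pad("EDF+C", 44),
    pad(n_rec, 8),
    pad(1, 8),                                  # record duration (s)
    pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(channel_labels, pad, "", n = 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(pad("AgAgCl electrode", 80), ns), con, eos = NULL)
  writeChar(strrep(pad("uV", 8), ns), con, eos = NULL)
  writeChar(strrep(pad(sprintf("%.6g", -pmax_), 8), ns), con, eos = NULL)
  writeChar(strrep(pad(sprintf("%.6g", pmax_), 8), ns), con, eos = NULL)
  writeChar(strrep(pad(dig_min, 8), ns), con, eos = NULL)
  writeChar(strrep(pad(dig_max, 8), ns), con, eos = NULL)
  writeChar(strrep(pad("", 80), ns), con, eos = NULL)   # prefiltering
  writeChar(strrep(pad(spr, 8), ns), con, eos = NULL)
  writeChar(strrep(pad("", 32), ns), con, eos = NULL)   # reserved

  scale <- (dig_max - dig_min) / (2 * pmax_)
  dig <- array(0L, dim = c(spr, ns, n_rec))
  for (j in seq_len(ns)) {
    d <- round((data[, j] + pmax_) * scale + dig_min)
    dig[, j, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                        # version
  rd(80); rd(80); rd(8); rd(8)                 # ids, date, time
  rd(8)                                        # header bytes
  rd(44)                                       # reserved / EDF+ flag
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)                # reserved

  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates not supported")
  unknown <- !(tolower(dims) %in% c("uv", "µv", ""))
  if (any(unknown))
    warning("unknown physical dimension '", dims[which(unknown)[1]],
            "'; assuming microvolts")

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  data <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (j in seq_len(ns)) {
    g <- (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
    data[, j] <- (as.vector(arr[, j, ]) - dmin[j]) * g + pmin_[j]
  }
  list(data = data, fs = spr[1] / rec_dur, channel_labels = labels)
}
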