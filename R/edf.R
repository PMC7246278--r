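# Minimal reader/writer for continuous EDF (European Data Format) recordings.
# EDF: 256-byte fixed ASCII header, 256 ASCII bytes per signal, then data
# records of 2-byte little-endian integers, scaled linearly from the digital
# to the physical range. Only what clinical spike review needs is supported:
# reading one signal from a continuous recording, and writing small synthetic
# files (used by the test-suite fixtures).

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[(from + 1):(from + len)]))
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 256L)
  if (length(hdr) < 256L)
    stop("corrupt EDF header: file shorter than 256 bytes", call. = FALSE)
  version <- edf_field(hdr, 0, 8)
  if (version != "0")
    stop("corrupt EDF header: version field is not '0'", call. = FALSE)
  n_records <- suppressWarnings(as.integer(edf_field(hdr, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(edf_field(hdr, 244, 8)))
  ns <- suppressWarnings(as.integer(edf_field(hdr, 252, 4)))
  if (is.na(ns) || ns < 1L || is.na(n_records) || is.na(rec_dur) || rec_dur <= 0)
    stop("corrupt EDF header: invalid record counts", call. = FALSE)
  sig <- readBin(con, "raw", n = 256L * ns)
  if (length(sig) < 256L * ns)
    stop("corrupt EDF header: truncated signal headers", call. = FALSE)
  fld <- function(from, len) {
    vapply(seq_len(ns) - 1L,
           function(i) edf_field(sig, from * ns + i * len, len), "")
  }
  list(
    ns = ns, n_records = n_records, record_duration = rec_dur,
    labels = fld(0, 16),
    phys_min = as.numeric(fld(16 + 80 + 8, 8)),
    phys_max = as.numeric(fld(16 + 80 + 8 + 8, 8)),
    dig_min = as.numeric(fld(16 + 80 + 8 + 16, 8)),
    dig_max = as.numeric(fld(16 + 80 + 8 + 24, 8)),
    samples_per_record = as.integer(fld(16 + 80 + 8 + 32 + 80, 8))
  )
}

#' Read one channel from an EDF file
#'
#' Supports continuous EDF recordings with 16-bit samples. Digital values are
#' rescaled to the physical (microvolt) range declared in the header.
#'
#' @param path Path to the `.edf` file.
#' @param channel Channel to extract: a label (matched against the signal
#'   labels in the header) or a 1-based signal index. Default: first signal.
#' @return An [eeg_channel] with the recorded sampling rate.
#' @export
read_edf <- function(path, channel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  h <- read_edf_header(path)
  if (is.character(channel)) {
    idx <- match(channel, h$labels)
    if (is.na(idx))
      stop("unknown channel '", channel, "'; file contains: ",
           paste(h$labels, collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(channel)
    if (is.na(idx) || idx < 1L || idx > h$ns)
      stop("unknown channel index ", channel, "; file contains ",
           h$ns, " signal(s)", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 256L + 256L * h$ns)
  spr <- h$samples_per_record
  out <- vector("list", h$n_records)
  for (r in seq_len(h$n_records)) {
    rec <- readBin(con, "integer", n = sum(spr), size = 2L,
                   signed = TRUE, endian = "little")
    if (length(rec) < sum(spr))
      stop("corrupt EDF file: truncated data record ", r, call. = FALSE)
    off <- c(0L, cumsum(spr))
    out[[r]] <- rec[(off[idx] + 1L):(off[idx] + spr[idx])]
  }
  dig <- unlist(out, use.names = FALSE)
  gain <- (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
  phys <- (dig - h$dig_min[idx]) * gain + h$phys_min[idx]
  eeg_channel(phys, fs = spr[idx] / h$record_duration,
              label = h$labels[idx])
}

#' Write channels to a minimal EDF file
#'
#' Writes a continuous EDF recording with one data record holding all samples.
#' The digital and physical ranges are set equal, so samples are stored as
#' rounded 16-bit integers: integer-valued traces in \[-32768, 32767\]
#' round-trip exactly. Intended for producing small synthetic test files, not
#' for clinical archiving.
#'
#' @param channels An [eeg_channel] or list of them; all must share the same
#'   length and sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path) {
  if (inherits(channels, "eeg_channel")) channels <- list(channels)
  ns <- length(channels)
  n <- length(channels[[1L]]$samples)
  fs <- channels[[1L]]$fs
  if (!all(vapply(channels, function(c) length(c$samples) == n, TRUE)) ||
      !all(vapply(channels, function(c) c$fs == fs, TRUE)))
    stop("all channels must share length and sampling rate", call. = FALSE)

  pad <- function(x, len) {
    x <- substr(as.character(x), 1L, len)
    formatC(x, width = len, flag = "-")
  }
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L + 256L * ns, 8), pad("", 44),
    pad(1L, 8), pad(format(n / fs, digits = 10), 8), pad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(channels, function(c) pad(c$label, 16), ""), collapse = ""),
    strrep(pad("", 80), ns),                    # transducer
    strrep(pad("uV", 8), ns),                   # physical dimension
    strrep(pad(-32768L, 8), ns),                # physical min
    strrep(pad(32767L, 8), ns),                 # physical max
    strrep(pad(-32768L, 8), ns),                # digital min
    strrep(pad(32767L, 8), ns),                 # digital max
    strrep(pad("", 80), ns),                    # prefiltering
    strrep(pad(n, 8), ns),                      # samples per record
    strrep(pad("", 32), ns)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (ch in channels) {
    dig <- as.integer(pmin(pmax(round(ch$samples), -32768), 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}
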