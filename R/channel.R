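#' A single EEG channel
#'
#' Container for one sampled voltage trace. All sample indices used throughout
#' the package are 0-based and intervals are half-open `[begin, end)`, so an
#' event `(100, 115)` covers samples 100..114.
#'
#' @param samples Numeric vector of voltage values (microvolts).
#' @param fs Sampling rate in Hz (default 200, the rate of typical clinical
#'   pediatric recordings this package targets).
#' @param label Channel name, e.g. a 10-20 electrode label such as `"Fp1"`.
#'
#' @return An object of class `eeg_channel`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' ch <- eeg_channel(sin(seq(0, 10, length.out = 400)), fs = 200, label = "Cz")
#' ch
#' @export
eeg_channel <- function(samples, fs = 200, label = "EEG") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("'samples' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1L]),
    class = "eeg_channel"
  )
}

#' @export
print.eeg_channel <- function(x, ...) {
  cat(sprintf("<eeg_channel> %s: %d samples @ %g Hz (%.2f s)\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.eeg_channel <- function(x) length(x$samples)

# coerce an eeg_channel or bare numeric vector to samples
as_samples <- function(x) {
  if (inherits(x, "eeg_channel")) x$samples else as.numeric(x)
}

#' Read a single-channel signal from plain text
#'
#' Reads a signal stored as one numeric value per line (lines starting with
#' `#` are ignored). This is the interchange format used for template files
#' and small fixtures.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz to attach to the channel.
#' @param label Channel label.
#' @return An [eeg_channel].
#' @seealso [write_signal_text()]
#' @export
read_signal_text <- function(path, fs = 200, label = "EEG") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no numeric data in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stop("non-numeric content in ", path, call. = FALSE)
  eeg_channel(vals, fs = fs, label = label)
}

#' Write a single-channel signal as plain text
#'
#' @param channel An [eeg_channel] or numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_text <- function(channel, path) {
  vals <- as_samples(channel)
  writeLines(format(vals, digits = 15, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
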