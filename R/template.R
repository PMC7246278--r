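#' Spike template
#'
#' The reference waveform an epileptic spike is matched against: a fixed-length
#' average of expert-annotated spike segments. The default length of 15
#' samples at 200 Hz covers a narrow interictal spike from onset to the end of
#' its after-going deflection.
#'
#' @param values Numeric waveform of the template.
#' @param fs Sampling rate in Hz.
#' @param n_source_segments How many segments were averaged to produce it.
#' @return An object of class `spike_template`.
#' @export
spike_template <- function(values, fs = 200, n_source_segments = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stop("template values must be finite and of length >= 2", call. = FALSE)
  if (all(values == 0))
    stop("template must not be all-zero", call. = FALSE)
  structure(
    list(values = values, fs = as.numeric(fs),
         n_source_segments = as.integer(n_source_segments)),
    class = "spike_template"
  )
}

#' @export
print.spike_template <- function(x, ...) {
  cat(sprintf("<spike_template> %d samples @ %g Hz, averaged from %s segment(s)\n",
              length(x$values), x$fs,
              ifelse(is.na(x$n_source_segments), "?", x$n_source_segments)))
  invisible(x)
}

#' Extract fixed-length spike segments from an annotated channel
#'
#' For every annotated event the absolute-amplitude peak inside
#' `[begin, end)` is located and a segment of `length` samples is cut from the
#' channel, centered on that peak (peak at index `length %/% 2`). Centering on
#' the peak aligns the sharp transients before averaging; without it the
#' average smears. Events whose centered segment would run past a channel edge
#' are skipped with a warning.
#'
#' @param channel An [eeg_channel].
#' @param annotations An [annotation_set] (0-based, half-open intervals).
#' @param length Segment length in samples (default 15).
#' @return A list of numeric vectors, each of `length` samples.
#' @export
extract_segments <- function(channel, annotations, length = 15L) {
  x <- as_samples(channel)
  L <- as.integer(length)
  if (L < 2L) stop("'length' must be >= 2", call. = FALSE)
  half <- L %/% 2L
  n <- base::length(x)
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    b <- annotations$begin[i]
    e <- min(annotations$end[i], n)
    if (b >= e || b < 0L) next
    seg <- x[(b + 1L):e]
    peak <- b + which.max(abs(seg)) - 1L      # 0-based global peak index
    start <- peak - half                      # 0-based segment start
    if (start < 0L || start + L > n) {
      warning(sprintf("event [%d,%d) too close to channel edge; skipped", b,
                      annotations$end[i]), call. = FALSE)
      next
    }
    out[[base::length(out) + 1L]] <- x[(start + 1L):(start + L)]
  }
  out
}

#' Align a segment on its absolute-amplitude peak
#'
#' Shifts a segment so its sample of maximal absolute amplitude sits at the
#' midpoint (`length %/% 2`). When the segment's position in its source
#' channel is supplied, the shifted-in samples are taken from the surrounding
#' channel context; otherwise zeros are shifted in.
#'
#' @param segment Numeric vector.
#' @param channel Optional source [eeg_channel] the segment was cut from.
#' @param begin Optional 0-based index of the segment's first sample within
#'   `channel`.
#' @return A numeric vector of the same length, peak-centered.
#' @export
align_on_peak <- function(segment, channel = NULL, begin = NULL) {
  segment <- as.numeric(segment)
  L <- length(segment)
  if (max(segment) == min(segment))
    stop("cannot align a constant segment", call. = FALSE)
  peak <- which.max(abs(segment)) - 1L        # 0-based within segment
  shift <- peak - L %/% 2L
  if (shift == 0L) return(segment)
  if (!is.null(channel) && !is.null(begin)) {
    x <- as_samples(channel)
    start <- as.integer(begin) + shift
    if (start < 0L || start + L > length(x))
      stop("aligned segment runs past the channel edge", call. = FALSE)
    return(x[(start + 1L):(start + L)])
  }
  padded <- c(rep(0, L), segment, rep(0, L))
  padded[(L + 1L + shift):(2L * L + shift)]
}

#' Average segments into a spike template
#'
#' Pointwise arithmetic mean of equal-length spike segments. No amplitude
#' normalization is applied here; the matched-filter score is normalized at
#' scoring time, so the template's absolute scale is irrelevant downstream.
#'
#' @param segments List of equal-length numeric vectors.
#' @param fs Sampling rate in Hz recorded on the template.
#' @return A [spike_template] with `n_source_segments = length(segments)`.
#' @export
build_template <- function(segments, fs = 200) {
  if (length(segments) == 0L)
    stop("need at least one segment", call. = FALSE)
  lens <- lengths(segments)
  if (length(unique(lens)) != 1L)
    stop("segments have ragged lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  m <- rowMeans(matrix(unlist(segments), nrow = lens[1L]))
  spike_template(m, fs = fs, n_source_segments = length(segments))
}

#' Write a template to a text file
#'
#' One value per line, preceded by `#`-prefixed metadata lines (`fs`,
#' `n_source_segments`).
#'
#' @param template A [spike_template].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  writeLines(c(
    sprintf("# fs: %g", template$fs),
    sprintf("# n_source_segments: %d", template$n_source_segments),
    format(template$values, digits = 15, trim = TRUE, scientific = FALSE)
  ), path)
  invisible(path)
}

#' Read a template written by [write_template()]
#'
#' @param path Template file path.
#' @return A [spike_template].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1L]))
  }
  vals <- suppressWarnings(as.numeric(lines[nzchar(lines) & !startsWith(lines, "#")]))
  if (length(vals) == 0L || anyNA(vals))
    stop("invalid template file: ", path, call. = FALSE)
  spike_template(vals, fs = get_meta("fs", 200),
                 n_source_segments = get_meta("n_source_segments", NA))
}
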