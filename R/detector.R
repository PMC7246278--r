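#' Detector configuration
#'
#' Holds the sliding-window and decision parameters of the matched-filter
#' scan. The defaults (window of 160 samples advanced by 5) decompose a
#' 2000-sample segment into 369 windows — an 800 ms analysis window at
#' 200 Hz, wide enough to hold a 15-sample spike with generous context —
#' with the similarity threshold 0.7 and a 20-sample duplicate-merging gap.
#'
#' @param window_size Window length in samples (default 160).
#' @param step Slide in samples between consecutive windows (default 5).
#' @param threshold Matched-filter similarity threshold in `(0, 1]`
#'   (default 0.7).
#' @param merge_gap Detections whose beginnings are closer than this many
#'   samples are treated as duplicates of one spike (default 20).
#' @param polarity Which spike polarities to accept: `"both"` (default),
#'   `"pos"` or `"neg"`.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(window_size = 160L, step = 5L, threshold = 0.7,
                            merge_gap = 20L, polarity = "both") {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  merge_gap <- as.integer(merge_gap)
  if (window_size < 2L) stop("'window_size' must be >= 2", call. = FALSE)
  if (step < 1L) stop("'step' must be >= 1", call. = FALSE)
  if (merge_gap < 0L) stop("'merge_gap' must be >= 0", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  polarity <- match.arg(polarity, c("both", "pos", "neg"))
  structure(list(window_size = window_size, step = step, threshold = threshold,
                 merge_gap = merge_gap, polarity = polarity),
            class = "detector_config")
}

#' Number of sliding windows over a signal
#'
#' `floor((n - window_size) / step) + 1`; trailing samples that do not fill a
#' whole window are dropped.
#'
#' @param n Signal length in samples.
#' @param window_size,step Window length and slide, in samples.
#' @return Integer window count (0 if the signal is shorter than one window).
#' @examples
#' n_windows(2000, 160, 5)  # 369
#' @export
n_windows <- function(n, window_size = 160L, step = 5L) {
  n <- as.numeric(n)
  ifelse(n < window_size, 0L,
         as.integer((n - window_size) %/% step + 1L))
}

#' Decompose a channel into sliding windows
#'
#' Windows start at 0, `step`, `2*step`, ... (0-based begins); each covers
#' `[begin, begin + window_size)`.
#'
#' @param channel An [eeg_channel] or numeric vector.
#' @param window_size,step Window length and slide, in samples.
#' @return A list with one element per window, each a list holding `begin`
#'   (0-based) and `samples`.
#' @export
sliding_windows <- function(channel, window_size = 160L, step = 5L) {
  x <- as_samples(channel)
  w <- as.integer(window_size)
  s <- as.integer(step)
  if (length(x) < w)
    stop("channel (", length(x), " samples) shorter than one window (",
         w, ")", call. = FALSE)
  begins <- seq.int(0L, length(x) - w, by = s)
  lapply(begins, function(b) list(begin = b, samples = x[(b + 1L):(b + w)]))
}

#' Scan a channel with the matched filter
#'
#' Slides the analysis window along the channel and scores every window with
#' [score_window()]; windows passing [review_threshold()] become raw
#' (pre-merge) detection events whose extent is the window's bounds. Because
#' consecutive windows overlap, a single spike typically produces a run of
#' adjacent detections — collapse them with [merge_detections()].
#'
#' @param channel An [eeg_channel] or numeric vector.
#' @param template A [spike_template] (or numeric waveform).
#' @param config A [detector_config].
#' @return A `data.frame` with columns `begin`, `end`, `score`, `confirmed`
#'   (`NA` until the classifier stage), ordered by `begin`.
#' @export
detect_spikes <- function(channel, template, config = detector_config()) {
  x <- as_samples(channel)
  mf <- create_matched_filter(template)
  w <- config$window_size
  if (w < mf$length)
    stop("'window_size' must be at least the template length", call. = FALSE)
  if (length(x) < w)
    stop("channel shorter than one window", call. = FALSE)
  # score every lag of the whole channel once; a window's score is the
  # signed max-|ncc| over the lags it contains
  cc <- ncc_profile(x, mf)
  begins <- seq.int(0L, length(x) - w, by = config$step)
  scores <- vapply(begins, function(b) {
    v <- cc[(b + 1L):(b + w - mf$length + 1L)]
    v[which.max(abs(v))]
  }, numeric(1))
  keep <- review_threshold(scores, config$threshold, config$polarity)
  out <- data.frame(begin = begins[keep], end = begins[keep] + w,
                    score = scores[keep], confirmed = rep(NA, sum(keep)))
  rownames(out) <- NULL
  out
}

#' Merge near-duplicate detections
#'
#' The overlap of consecutive windows makes one spike (or a spike with its
#' after-going slow wave) fire many windows. Detections are grouped
#' transitively: a detection joins the current group when its beginning is
#' less than `merge_gap` samples after the previous detection's beginning,
#' so an unbroken run of closely spaced detections — the signature of a
#' single underlying transient — collapses to one event. A merged event
#' keeps the group's earliest begin, latest end and the score of largest
#' magnitude. Idempotent: merging a merged list changes nothing.
#'
#' @param events Detection `data.frame` sorted by `begin`
#'   (as from [detect_spikes()]).
#' @param merge_gap Gap in samples below which beginnings count as
#'   duplicates (default 20).
#' @return A merged detection `data.frame` whose consecutive beginnings
#'   differ by at least `merge_gap`.
#' @export
merge_detections <- function(events, merge_gap = 20L) {
  if (nrow(events) == 0L) return(events)
  if (is.unsorted(events$begin))
    stop("'events' must be sorted by begin", call. = FALSE)
  grp <- cumsum(c(TRUE, diff(events$begin) >= merge_gap))
  idx <- split(seq_len(nrow(events)), grp)
  merged <- lapply(idx, function(i) {
    sc <- events$score[i]
    data.frame(begin = min(events$begin[i]), end = max(events$end[i]),
               score = sc[which.max(abs(sc))],
               confirmed = if (all(is.na(events$confirmed[i]))) NA
                           else any(events$confirmed[i], na.rm = TRUE))
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}
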