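#' Confusion counts
#'
#' Holds TP/FP/FN/TN tallies at either the event level (matched detections
#' against annotated spikes; TN is undefined there and stored as `NA`) or the
#' window level (per-window H1 decisions against per-window truth).
#'
#' @param tp,fp,fn,tn Non-negative counts; `tn` may be `NA` at event level.
#' @param level `"event"` or `"window"`.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = NA_integer_,
                             level = c("event", "window")) {
  level <- match.arg(level)
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(vals < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn), level = level),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts/%s> TP=%d FP=%d FN=%d TN=%s\n",
              x$level, x$tp, x$fp, x$fn,
              ifelse(is.na(x$tn), "-", x$tn)))
  invisible(x)
}

#' Match detections against ground-truth events
#'
#' Greedy one-to-one matching in order of detection begin: a detection whose
#' interval, expanded by `tolerance` samples on both sides, overlaps a
#' not-yet-matched truth event is a true positive (matched to the earliest
#' such truth). Detections left unmatched are false positives; truths left
#' unmatched are false negatives. Each truth event can absorb at most one
#' detection, so duplicated detections of the same spike count as false
#' positives.
#'
#' @param detected Detection `data.frame` (`begin`, `end`), sorted by begin.
#' @param truth An [annotation_set] (or `data.frame` with `begin`, `end`).
#' @param tolerance Slack in samples added to each side of a detection
#'   before testing overlap (default 0).
#' @return Event-level [confusion_counts].
#' @export
match_events <- function(detected, truth, tolerance = 0L) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  matched <- rep(FALSE, nt)
  tp <- 0L
  if (nd > 0L) {
    ord <- order(detected$begin, detected$end)
    for (i in ord) {
      lo <- detected$begin[i] - tolerance
      hi <- detected$end[i] + tolerance
      hit <- which(!matched & truth$begin < hi & truth$end > lo)
      if (length(hit) > 0L) {
        matched[hit[1L]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  confusion_counts(tp = tp, fp = nd - tp, fn = sum(!matched),
                   tn = NA_integer_, level = "event")
}

#' Window-level confusion counts
#'
#' Tallies the standard 2x2 table over parallel per-window decision and
#' truth vectors.
#'
#' @param decisions Logical vector: H1 decision per window.
#' @param truth_windows Logical vector of the same length: whether each
#'   window truly contains (part of) a spike.
#' @return Window-level [confusion_counts].
#' @export
window_confusion <- function(decisions, truth_windows) {
  decisions <- as.logical(decisions)
  truth_windows <- as.logical(truth_windows)
  if (length(decisions) != length(truth_windows))
    stop("'decisions' and 'truth_windows' must have equal length",
         call. = FALSE)
  confusion_counts(
    tp = sum(decisions & truth_windows),
    fp = sum(decisions & !truth_windows),
    fn = sum(!decisions & truth_windows),
    tn = sum(!decisions & !truth_windows),
    level = "window"
  )
}

ratio_pct <- function(num, den) {
  if (is.na(den) || den == 0) return(NA_real_)
  100 * num / den
}

#' Sensitivity, specificity and precision
#'
#' Percentages computed at full precision: sensitivity
#' `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, precision
#' `100*TP/(TP+FP)`. A zero (or undefined) denominator yields `NA` rather
#' than 0. Round only for display.
#'
#' @param counts A [confusion_counts].
#' @return A single percentage in \[0, 100\], or `NA` when undefined.
#' @examples
#' sensitivity(confusion_counts(tp = 51, fn = 5))          # 91.07...
#' specificity(confusion_counts(fp = 53, tn = 36847, level = "window"))
#' @export
sensitivity <- function(counts) ratio_pct(counts$tp, counts$tp + counts$fn)

#' @rdname sensitivity
#' @export
specificity <- function(counts) ratio_pct(counts$tn, counts$tn + counts$fp)

#' @rdname sensitivity
#' @export
precision <- function(counts) ratio_pct(counts$tp, counts$tp + counts$fp)

#' Evaluate detections against truth at both levels
#'
#' Convenience wrapper producing one report from a detection run: event-level
#' matching via [match_events()] and the derived percentages.
#'
#' @param detected Detection `data.frame`.
#' @param truth An [annotation_set].
#' @param tolerance Matching slack in samples (default 160, one analysis
#'   window).
#' @return A list with `counts` ([confusion_counts]) and `sensitivity`,
#'   `precision` percentages.
#' @export
evaluate_detections <- function(detected, truth, tolerance = 160L) {
  counts <- match_events(detected, truth, tolerance)
  list(counts = counts,
       sensitivity = sensitivity(counts),
       precision = precision(counts))
}

#' Sweep the detection threshold
#'
#' Re-runs the matched-filter scan at each threshold over the same windows
#' and merging rule, reporting event-level sensitivity (merged detections
#' matched one-to-one against truth with `tolerance = window_size`) and
#' window-level specificity (a window counts as truly spike-bearing when it
#' overlaps an annotated event). Raising the threshold can only shrink the
#' detection set, so specificity is non-decreasing in the threshold.
#'
#' @param channel An [eeg_channel] or numeric vector.
#' @param template A [spike_template].
#' @param truth An [annotation_set] for the channel.
#' @param thresholds Numeric vector of thresholds in `(0, 1]`.
#' @param config A [detector_config]; its `threshold` field is overridden by
#'   each sweep value.
#' @return `data.frame` with one row per threshold: `threshold`,
#'   `n_detections` (pre-merge), `n_events` (post-merge), `sensitivity`,
#'   `specificity`.
#' @export
threshold_sweep <- function(channel, template, truth, thresholds,
                            config = detector_config()) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("'thresholds' must be in (0, 1]", call. = FALSE)
  x <- as_samples(channel)
  mf <- create_matched_filter(template)
  cc <- ncc_profile(x, mf)
  w <- config$window_size
  begins <- seq.int(0L, length(x) - w, by = config$step)
  scores <- vapply(begins, function(b) {
    v <- cc[(b + 1L):(b + w - mf$length + 1L)]
    v[which.max(abs(v))]
  }, numeric(1))
  truth_win <- vapply(begins, function(b)
    any(truth$begin < b + w & truth$end > b), logical(1))

  rows <- lapply(thresholds, function(th) {
    keep <- review_threshold(scores, th, config$polarity)
    det <- data.frame(begin = begins[keep], end = begins[keep] + w,
                      score = scores[keep], confirmed = rep(NA, sum(keep)))
    merged <- merge_detections(det, config$merge_gap)
    ev <- match_events(merged, truth, tolerance = w)
    wc <- window_confusion(keep, truth_win)
    data.frame(threshold = th, n_detections = sum(keep),
               n_events = nrow(merged),
               sensitivity = sensitivity(ev), specificity = specificity(wc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
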