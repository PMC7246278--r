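#' Build an annotation set
#'
#' Annotations mark expert-reviewed abnormal segments (spikes,
#' spike-and-slow-wave complexes) as half-open sample intervals
#' `[begin, end)` with 0-based indices. Events are kept sorted by `begin`.
#'
#' @param begin,end Integer sample indices, `0 <= begin < end`.
#' @param label Character label per event (default `"spike"`).
#' @param channel Optional channel name the annotations refer to.
#' @return A `data.frame` of class `annotation_set` with columns
#'   `begin`, `end`, `label`, sorted by `begin`.
#' @export
annotation_set <- function(begin = integer(), end = integer(),
                           label = "spike", channel = NA_character_) {
  begin <- as.integer(begin)
  end <- as.integer(end)
  if (length(begin) != length(end))
    stop("'begin' and 'end' must have the same length", call. = FALSE)
  if (any(begin < 0L)) stop("negative 'begin' index", call. = FALSE)
  if (any(begin >= end))
    stop("each event must satisfy begin < end", call. = FALSE)
  out <- data.frame(begin = begin, end = end,
                    label = rep_len(as.character(label), length(begin)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$begin, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channel") <- channel
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Read ground-truth annotations from CSV
#'
#' Expects a header `begin,end,label` (a `label` column is optional); indices
#' are 0-based, intervals half-open. Rows are returned sorted by `begin`.
#'
#' @param path CSV file path.
#' @param channel Optional channel name to attach.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, channel = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("begin", "end") %in% names(df)))
    stop("annotation CSV must have columns 'begin' and 'end'", call. = FALSE)
  lab <- if ("label" %in% names(df)) df$label else "spike"
  annotation_set(df$begin, df$end, label = lab, channel = channel)
}

#' Write annotations to CSV
#'
#' @param annotations An [annotation_set] or data.frame with `begin`, `end`
#'   (and optionally `label`) columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)[, intersect(c("begin", "end", "label"),
                                               names(annotations)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detection events to CSV
#'
#' Emits columns `begin,end,score,confirmed`; `confirmed` is empty (`NA`) for
#' detections that have not passed through the neural-network stage.
#'
#' @param events A detection `data.frame` as returned by [detect_spikes()],
#'   [merge_detections()] or [detect_and_confirm()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(events, path) {
  df <- data.frame(
    begin = as.integer(events$begin),
    end = as.integer(events$end),
    score = events$score,
    confirmed = if ("confirmed" %in% names(events)) events$confirmed else NA
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detection events from CSV
#'
#' Counterpart of [write_detections()].
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `begin`, `end`, `score`, `confirmed`,
#'   sorted by `begin`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("begin", "end") %in% names(df)))
    stop("detection CSV must have columns 'begin' and 'end'", call. = FALSE)
  if (any(df$begin >= df$end))
    stop("each detection must satisfy begin < end", call. = FALSE)
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"confirmed" %in% names(df)) df$confirmed <- NA
  df <- df[order(df$begin, df$end), c("begin", "end", "score", "confirmed")]
  rownames(df) <- NULL
  df
}
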