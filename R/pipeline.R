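#' Detect spikes and confirm them with the neural network
#'
#' The full two-stage pipeline: (i) sliding-window analysis of the channel,
#' (ii) matched-filter detection and duplicate merging, (iii) confirmation of
#' each merged candidate by the trained MLP. For every merged event a window
#' of `config$window_size` samples is re-extracted at the event's begin
#' (clamped so it fits inside the channel), its features are computed with
#' the same extractor used at training time, and the classifier's verdict is
#' recorded. Rejected candidates are kept in the output with
#' `confirmed = FALSE` so a reviewer can still inspect them; the classifier
#' can only ever remove candidates, never add them.
#'
#' @param channel An [eeg_channel] or numeric vector.
#' @param template A [spike_template].
#' @param model A trained [mlp_model][train_mlp()] whose positive class is
#'   `"spike"`.
#' @param config A [detector_config].
#' @return A `data.frame` with columns `begin`, `end`, `score`, `confirmed`
#'   (logical) and `confidence` (classifier activation for the predicted
#'   class), ordered by `begin`.
#' @export
detect_and_confirm <- function(channel, template, model,
                               config = detector_config()) {
  x <- as_samples(channel)
  raw <- tryCatch(detect_spikes(x, template, config),
                  error = function(e) stop("detector stage: ",
                                           conditionMessage(e), call. = FALSE))
  events <- merge_detections(raw, config$merge_gap)
  if (nrow(events) == 0L) {
    events$confirmed <- logical(0)
    events$confidence <- numeric(0)
    return(events)
  }
  w <- config$window_size
  starts <- pmin(pmax(events$begin, 0L), length(x) - w)
  feats <- t(vapply(starts,
                    function(b) extract_features(x[(b + 1L):(b + w)]),
                    numeric(8L)))
  pred <- tryCatch(predict(model, feats),
                   error = function(e) stop("classifier stage: ",
                                            conditionMessage(e), call. = FALSE))
  events$confirmed <- pred$class == "spike"
  events$confidence <- pred$confidence
  events
}
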