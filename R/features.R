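#' Names of the window features
#'
#' @return Character vector naming, in order, the features computed by
#'   [extract_features()].
#' @export
feature_names <- function() {
  c("mean", "sd", "skewness", "kurtosis", "peak_to_peak",
    "line_length", "energy", "zero_crossings")
}

#' Statistical features of one analysis window
#'
#' Computes the fixed 8-feature summary used to discriminate spike-bearing
#' windows from background activity:
#' mean, standard deviation, skewness, excess kurtosis, peak-to-peak
#' amplitude, line length (`sum(|diff(x)|)`, a standard EEG complexity
#' measure), signal energy (`sum(x^2)`) and the zero-crossing count of the
#' mean-removed window. Zero-variance moments of a constant window are
#' reported as 0 rather than `NaN`.
#'
#' @param window Numeric vector of at least 2 samples.
#' @return Named numeric vector of length 8 (names from [feature_names()]).
#' @examples
#' extract_features(c(0, 1, 0, -1))
#' @export
extract_features <- function(window) {
  x <- as_samples(window)
  if (length(x) < 2L) stop("window must have >= 2 samples", call. = FALSE)
  s <- stats::sd(x)
  if (s > 0) {
    skew <- e1071::skewness(x)
    kurt <- e1071::kurtosis(x)
  } else {
    skew <- 0
    kurt <- 0
  }
  centered <- x - mean(x)
  zc <- sum(centered[-length(centered)] * centered[-1L] < 0)
  out <- c(mean(x), s, skew, kurt, max(x) - min(x),
           sum(abs(diff(x))), sum(x^2), zc)
  names(out) <- feature_names()
  out
}

# feature matrix for a list/matrix of windows
extract_features_many <- function(windows) {
  if (is.matrix(windows)) windows <- asplit(windows, 1L)
  t(vapply(windows, extract_features, numeric(8L)))
}
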