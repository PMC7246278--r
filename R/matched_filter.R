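#' Create a matched filter from a spike template
#'
#' The matched filter's impulse response is the time-reversed template, the
#' classical choice that maximizes output signal-to-noise ratio for a known
#' waveform in additive noise. The template's energy (sum of squares) is kept
#' for normalization: scores are normalized cross-correlations in
#' \[-1, 1\], which makes the detection threshold scale-invariant.
#'
#' @param template A [spike_template].
#' @return An object of class `matched_filter` with elements `coefficients`
#'   (reversed template), `template` (original waveform), `template_energy`
#'   and `length`.
#' @examples
#' mf <- create_matched_filter(spike_template(c(1, 2, 3)))
#' mf$coefficients   # 3 2 1
#' mf$template_energy  # 14
#' @export
create_matched_filter <- function(template) {
  if (!inherits(template, "spike_template"))
    template <- spike_template(template)
  v <- template$values
  energy <- sum(v^2)
  if (energy == 0) stop("template must not be all-zero", call. = FALSE)
  structure(
    list(coefficients = rev(v), template = v,
         template_energy = energy, length = length(v)),
    class = "matched_filter"
  )
}

#' @export
print.matched_filter <- function(x, ...) {
  cat(sprintf("<matched_filter> length %d, template energy %.4g\n",
              x$length, x$template_energy))
  invisible(x)
}

# Normalized cross-correlation of the template against every L-sample
# sub-segment of x. Returns a vector of length(x) - L + 1; entry k+1 is the
# score at 0-based lag k. Sub-segments with zero energy score 0.
ncc_profile <- function(x, mf) {
  L <- mf$length
  n <- length(x)
  if (n < L)
    stop("signal shorter than the filter (", n, " < ", L, ")", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  # embed() row i holds x[i+L-1], ..., x[i]; dotted with the reversed
  # template this is the plain cross-correlation at lag i-1
  subs <- stats::embed(x, L)
  num <- as.vector(subs %*% mf$coefficients)
  sub_energy <- rowSums(subs^2)
  den <- sqrt(mf$template_energy * sub_energy)
  score <- numeric(length(num))
  ok <- den > 0
  score[ok] <- num[ok] / den[ok]
  score
}

#' Score one window against the matched filter
#'
#' Slides the template over every lag inside the window and computes the
#' normalized cross-correlation
#' `sum(template * sub) / sqrt(template_energy * sub_energy)` for each
#' L-sample sub-segment. The window's score is the signed value of maximal
#' absolute magnitude over all lags; `|score| = 1` iff some sub-segment is an
#' exact (positively or negatively) scaled copy of the template.
#'
#' @param window Numeric vector, length at least the filter length.
#' @param mf A [matched_filter].
#' @return A list with `score` (in \[-1, 1\]) and `best_lag` (0-based offset
#'   of the best-matching sub-segment within the window).
#' @export
score_window <- function(window, mf) {
  cc <- ncc_profile(as_samples(window), mf)
  k <- which.max(abs(cc))
  list(score = cc[k], best_lag = k - 1L)
}

#' Threshold decision on a matched-filter score
#'
#' Decides H1 (spike present) when the score reaches the similarity
#' threshold. The comparison is inclusive (`>=`). By default both polarities
#' are accepted (`|score| >= thresh`), since the sign of a spike depends on
#' montage and reference; restrict with `polarity`.
#'
#' @param score Numeric score(s) in \[-1, 1\].
#' @param thresh Threshold in `(0, 1]`; default 0.7.
#' @param polarity `"both"` (default), `"pos"` or `"neg"`.
#' @return Logical vector: `TRUE` where the spike hypothesis is accepted.
#' @export
review_threshold <- function(score, thresh = 0.7, polarity = c("both", "pos", "neg")) {
  if (!is.numeric(thresh) || length(thresh) != 1L || is.na(thresh) ||
      thresh <= 0 || thresh > 1)
    stop("'thresh' must be in (0, 1]", call. = FALSE)
  polarity <- match.arg(polarity)
  switch(polarity,
         both = abs(score) >= thresh,
         pos = score >= thresh,
         neg = score <= -thresh)
}
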