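#' Simulation configuration
#'
#' Conditions for the synthetic EEG generator. Defaults mirror a typical
#' evaluation segment: 2000 samples (10 s) at 200 Hz carrying 7 spikes, with
#' spike peaks at 8 background standard deviations — a clearly epileptiform
#' amplitude against the base rhythm — at least one second apart.
#'
#' @param duration Trace length in samples (default 2000).
#' @param fs Sampling rate in Hz (default 200).
#' @param n_spikes Number of spikes to inject (default 7).
#' @param spike_amplitude Spike peak amplitude as a multiple of the
#'   background standard deviation (default 8).
#' @param slow_wave_fraction Fraction of injected spikes carrying a trailing
#'   slow wave (default 0).
#' @param min_gap Minimum gap in samples between the end of one spike and
#'   the beginning of the next (default 200, i.e. 1 s).
#' @param spike_length Spike waveform length in samples (default 15).
#' @param seed Optional integer seed; a fixed seed fixes the output exactly.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration = 2000L, fs = 200, n_spikes = 7L,
                              spike_amplitude = 8, slow_wave_fraction = 0,
                              min_gap = 200L, spike_length = 15L,
                              seed = NULL) {
  duration <- as.integer(duration)
  n_spikes <- as.integer(n_spikes)
  min_gap <- as.integer(min_gap)
  spike_length <- as.integer(spike_length)
  if (duration < 1L) stop("'duration' must be positive", call. = FALSE)
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (n_spikes < 0L) stop("'n_spikes' must be >= 0", call. = FALSE)
  if (spike_amplitude < 0) stop("'spike_amplitude' must be >= 0", call. = FALSE)
  if (slow_wave_fraction < 0 || slow_wave_fraction > 1)
    stop("'slow_wave_fraction' must be in [0, 1]", call. = FALSE)
  if (min_gap < 0L) stop("'min_gap' must be >= 0", call. = FALSE)
  if (n_spikes * (spike_length + min_gap) > duration)
    stop("cannot place ", n_spikes, " spikes of ", spike_length,
         " samples with gap ", min_gap, " in ", duration, " samples",
         call. = FALSE)
  structure(list(duration = duration, fs = fs, n_spikes = n_spikes,
                 spike_amplitude = spike_amplitude,
                 slow_wave_fraction = slow_wave_fraction,
                 min_gap = min_gap, spike_length = spike_length,
                 seed = seed),
            class = "simulation_config")
}

#' Generate the background EEG rhythm
#'
#' Emulates the base rhythm against which spikes are detected: seeded white
#' noise band-limited to 0.5-30 Hz (4th-order Butterworth, zero-phase) plus
#' a sinusoidal alpha component with frequency drawn in 8-12 Hz and random
#' phase. The trace is rescaled to unit standard deviation, so spike
#' amplitudes expressed in background standard deviations are literal.
#'
#' @param config A [simulation_config].
#' @return An [eeg_channel] labeled `"synthetic"`.
#' @export
generate_background <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$duration
  fs <- config$fs
  w <- stats::rnorm(n)
  bf <- signal::butter(4, c(0.5, 30) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, w))
  x <- x / stats::sd(x)
  f_alpha <- stats::runif(1, 8, 12)
  phase <- stats::runif(1, 0, 2 * pi)
  x <- x + 0.5 * sin(2 * pi * f_alpha * seq_len(n) / fs + phase)
  eeg_channel(x / stats::sd(x), fs = fs, label = "synthetic")
}

#' Canonical synthetic spike waveform
#'
#' A deterministic, sharp, asymmetric biphasic transient peaking at the
#' midpoint: a fast two-sample upstroke to the peak followed by an immediate
#' after-going undershoot that decays back to baseline — the morphology of a
#' narrow interictal spike (~35 ms main deflection at 200 Hz). Peak
#' amplitude is 1; scale at injection time. With `slow_wave = TRUE` a
#' half-sine slow wave of 4x the spike duration and one third of its
#' amplitude is appended, giving a spike-and-slow-wave complex.
#'
#' @param length Spike length in samples (default 15, minimum 5).
#' @param polarity `1` for a positive peak, `-1` for pointwise negation.
#' @param slow_wave Append a trailing slow wave?
#' @return Numeric waveform with attribute `core_length` = `length` (the
#'   extent of the spike proper, used for ground-truth annotations).
#' @export
generate_spike_waveform <- function(length = 15L, polarity = 1,
                                    slow_wave = FALSE) {
  L <- as.integer(length)
  if (L < 5L) stop("'length' must be >= 5", call. = FALSE)
  p <- L %/% 2L                                 # 0-based peak index
  y <- numeric(L)
  # transient relative to the peak: fast rise, sharp fall with undershoot
  rel <- c(-2, -1, 0, 1, 2, 3)
  amp <- c(0.1, 0.55, 1, -0.55, -0.25, -0.08)
  idx <- p + rel
  keep <- idx >= 0L & idx < L
  y[idx[keep] + 1L] <- amp[keep]
  if (slow_wave) {
    lw <- 4L * L
    y <- c(y, (1 / 3) * sin(pi * seq_len(lw) / lw))
  }
  y <- y * polarity
  attr(y, "core_length") <- L
  y
}

# seeded placement of n begins in [0, total - len] with pairwise
# begin-to-begin distance >= len + gap
place_spikes <- function(n, total, len, gap) {
  if (n == 0L) return(integer(0))
  slack <- total - n * len - (n - 1L) * gap
  if (slack < 0L) stop("infeasible spike placement", call. = FALSE)
  offsets <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  offsets + (seq_len(n) - 1L) * (len + gap)
}

#' Inject spike waveforms into a background trace
#'
#' Adds the waveform, scaled to `spike_amplitude` background standard
#' deviations, at seeded random positions that respect `min_gap`, and
#' returns exact ground truth. Annotation intervals cover the spike proper
#' (`core_length` samples, half-open), not the trailing slow wave.
#'
#' @param background An [eeg_channel] (typically from
#'   [generate_background()]).
#' @param waveform Spike waveform with unit peak (from
#'   [generate_spike_waveform()]).
#' @param config A [simulation_config]; `n_spikes`, `spike_amplitude`,
#'   `slow_wave_fraction`, `min_gap` and `seed` are honored.
#' @return A list with `channel` (the spiked [eeg_channel]) and `truth`
#'   (an [annotation_set] of the injected positions).
#' @export
inject_spikes <- function(background, waveform = generate_spike_waveform(),
                          config = simulation_config()) {
  x <- as_samples(background)
  n <- config$n_spikes
  core <- attr(waveform, "core_length")
  if (is.null(core)) core <- length(waveform)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  if (n == 0L)
    return(list(channel = eeg_channel(x, fs = background$fs,
                                      label = background$label),
                truth = annotation_set()))

  sw <- generate_spike_waveform(core, polarity = sign(waveform[which.max(abs(waveform))]),
                                slow_wave = TRUE)
  with_sw <- stats::runif(n) < config$slow_wave_fraction
  # reserve room for the longest injected shape
  max_len <- if (any(with_sw)) length(sw) else length(waveform)
  begins <- place_spikes(n, length(x) - (max_len - core), core, config$min_gap)
  scale <- config$spike_amplitude * stats::sd(x)
  for (i in seq_len(n)) {
    wf <- if (with_sw[i]) sw else waveform
    span <- (begins[i] + 1L):(begins[i] + length(wf))
    x[span] <- x[span] + scale * wf
  }
  list(channel = eeg_channel(x, fs = background$fs, label = background$label),
       truth = annotation_set(begins, begins + core,
                              label = ifelse(with_sw, "spike_slow_wave", "spike"),
                              channel = background$label))
}

#' Simulate an annotated EEG segment
#'
#' One-call convenience: background rhythm plus injected spikes with ground
#' truth.
#'
#' @param config A [simulation_config].
#' @return A list with `channel` and `truth`, as in [inject_spikes()].
#' @export
simulate_eeg <- function(config = simulation_config()) {
  bg <- generate_background(config)
  inject_spikes(bg, generate_spike_waveform(config$spike_length), config)
}

#' Generate a labeled feature dataset
#'
#' Builds the training material for the confirmation network:
#' `n_per_class` windows containing an injected spike (at a seeded random
#' position inside the window, amplitude per the config) and `n_per_class`
#' background-only windows, each summarized by [extract_features()].
#'
#' @param n_per_class Examples per class (default 400).
#' @param config A [simulation_config]; `fs`, `spike_amplitude` and `seed`
#'   are honored.
#' @param window_size Window length in samples (default 160, the detector's
#'   analysis window).
#' @return `data.frame` of the 8 feature columns plus a `label` column with
#'   values `"spike"` and `"background"`.
#' @export
generate_labeled_dataset <- function(n_per_class = 400L,
                                     config = simulation_config(),
                                     window_size = 160L) {
  n <- as.integer(n_per_class)
  w <- as.integer(window_size)
  L <- config$spike_length
  big <- simulation_config(duration = 2L * n * w, fs = config$fs,
                           n_spikes = 0L, seed = config$seed)
  bg <- as_samples(generate_background(big))
  wf <- generate_spike_waveform(L)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  pos <- sample.int(w - L - 20L, n, replace = TRUE) + 10L  # offset in window
  scale <- config$spike_amplitude            # background has unit sd
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    win <- bg[((i - 1L) * w + 1L):(i * w)]
    win[(pos[i] + 1L):(pos[i] + L)] <- win[(pos[i] + 1L):(pos[i] + L)] + scale * wf
    rows[[i]] <- extract_features(win)
  }
  for (i in seq_len(n)) {
    rows[[n + i]] <- extract_features(bg[((n + i - 1L) * w + 1L):((n + i) * w)])
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- rep(c("spike", "background"), each = n)
  out
}
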