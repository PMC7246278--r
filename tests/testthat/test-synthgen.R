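test_that("background generation is seeded, unit-variance and band-limited", {
  cfg <- simulation_config(seed = 42)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$samples, b$samples)
  expect_length(a, 2000)

  sds <- vapply(1:10, function(s)
    sd(generate_background(simulation_config(seed = s))$samples), 0)
  expect_true(all(abs(sds - 1) <= 0.1))
})

test_that("background rarely resembles the spike template", {
  # false-alarm calibration: at default settings at least 99% of analysis
  # windows of pure background score below the 0.7 detection threshold
  mf <- create_matched_filter(spike_template(generate_spike_waveform(15)))
  over <- vapply(1:10, function(s) {
    x <- generate_background(simulation_config(seed = s))$samples
    det <- detect_spikes(x, spike_template(generate_spike_waveform(15)),
                         detector_config(threshold = 0.7))
    nrow(det) / n_windows(length(x))
  }, 0)
  expect_lt(mean(over), 0.01)
})

test_that("the spike waveform has the canonical narrow-spike morphology", {
  wf <- generate_spike_waveform(15)
  expect_length(wf, 15L)
  expect_equal(which.max(abs(wf)), 8L)          # single dominant peak, centered
  expect_equal(max(wf), 1)
  expect_equal(sum(abs(wf) == 1), 1L)

  expect_equal(as.numeric(generate_spike_waveform(15, polarity = -1)),
               -as.numeric(generate_spike_waveform(15)))

  # deterministic shape generator: independent calls correlate perfectly
  expect_equal(cor(generate_spike_waveform(15), generate_spike_waveform(15)), 1)

  sw <- generate_spike_waveform(15, slow_wave = TRUE)
  expect_length(sw, 15L + 60L)                  # half-sine of 4x the duration
  expect_equal(attr(sw, "core_length"), 15L)
  expect_lte(max(abs(sw[16:75])), 1 / 3 + 1e-9)
  expect_error(generate_spike_waveform(3), ">= 5")
})

test_that("injection respects gaps and records exact ground truth", {
  cfg <- simulation_config(seed = 7)
  bg <- generate_background(cfg)
  out <- inject_spikes(bg, generate_spike_waveform(15), cfg)
  expect_equal(nrow(out$truth), 7L)
  expect_true(all(diff(out$truth$begin) >= 15 + cfg$min_gap))
  expect_equal(out$truth$end - out$truth$begin, rep(15L, 7))
  # the injected difference signal is exactly the scaled waveform
  delta <- out$channel$samples - bg$samples
  b <- out$truth$begin[3]
  expect_equal(delta[(b + 1):(b + 15)],
               cfg$spike_amplitude * sd(bg$samples) *
                 as.numeric(generate_spike_waveform(15)))
  expect_true(all(abs(delta[setdiff(seq_along(delta),
                                    unlist(Map(seq, out$truth$begin + 1,
                                               out$truth$end)))]) < 1e-12))
})

test_that("zero spikes leaves the channel untouched", {
  cfg <- simulation_config(n_spikes = 0, seed = 8)
  bg <- generate_background(cfg)
  out <- inject_spikes(bg, generate_spike_waveform(15), cfg)
  expect_identical(out$channel$samples, bg$samples)
  expect_equal(nrow(out$truth), 0L)
})

test_that("infeasible placements are rejected up front", {
  expect_error(simulation_config(duration = 100, n_spikes = 7, min_gap = 200),
               "cannot place")
})

test_that("high-amplitude spikes are fully recovered by the detector", {
  cfg <- simulation_config(seed = 9, spike_amplitude = 10)
  sim <- simulate_eeg(cfg)
  det <- merge_detections(detect_spikes(sim$channel, fixture_template(),
                                        detector_config()), 20)
  cc <- match_events(det, sim$truth, tolerance = 160)
  expect_equal(cc$tp, 7L)
  expect_equal(cc$fn, 0L)
})

test_that("spike-and-slow-wave complexes merge into single events", {
  cfg <- simulation_config(seed = 10, slow_wave_fraction = 1)
  sim <- simulate_eeg(cfg)
  expect_true(all(sim$truth$label == "spike_slow_wave"))
  det <- merge_detections(detect_spikes(sim$channel, fixture_template(),
                                        detector_config()), 20)
  cc <- match_events(det, sim$truth, tolerance = 160)
  expect_equal(cc$fn, 0L)
})

test_that("the labeled dataset has the expected size and is seeded", {
  ds <- fixture_dataset()
  expect_equal(nrow(ds), 800L)
  expect_equal(as.integer(table(ds$label)), c(400L, 400L))
  expect_named(ds, c(feature_names(), "label"))
  small1 <- generate_labeled_dataset(20, simulation_config(seed = 3))
  small2 <- generate_labeled_dataset(20, simulation_config(seed = 3))
  expect_identical(small1, small2)
})

test_that("detection sensitivity rises with spike amplitude", {
  tpl <- fixture_template()
  sens_at <- function(amp) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_eeg(simulation_config(seed = 1000 + s,
                                            spike_amplitude = amp))
      det <- merge_detections(detect_spikes(sim$channel, tpl,
                                            detector_config()), 20)
      sensitivity(match_events(det, sim$truth, tolerance = 160)) / 100
    }, 0))
  }
  s2 <- sens_at(2); s4 <- sens_at(4); s8 <- sens_at(8)
  expect_lte(s2, s4)
  expect_lte(s4, s8)
  expect_equal(s8, 1)
})
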