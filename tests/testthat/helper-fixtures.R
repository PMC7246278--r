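# Shared synthetic fixtures, built once per test run.
# The template comes from a 6000-sample annotated training trace carrying 25
# spikes; the confirmation model is trained on the 400 + 400 labeled window
# dataset. Both use seeds unrelated to the evaluation traces used in tests.

fixture_cache <- new.env(parent = emptyenv())

fixture_template <- function() {
  if (is.null(fixture_cache$template)) {
    cfg <- simulation_config(duration = 6000, n_spikes = 25, seed = 11)
    sim <- simulate_eeg(cfg)
    segs <- extract_segments(sim$channel, sim$truth, 15)
    fixture_cache$template <- build_template(segs)
  }
  fixture_cache$template
}

fixture_dataset <- function() {
  if (is.null(fixture_cache$dataset)) {
    fixture_cache$dataset <-
      generate_labeled_dataset(400, simulation_config(seed = 3))
  }
  fixture_cache$dataset
}

fixture_model <- function() {
  if (is.null(fixture_cache$model)) {
    split <- split_train_test(fixture_dataset(), 0.7, seed = 5)
    fixture_cache$model <- train_mlp(split$train, seed = 9)
    fixture_cache$model_test <- split$test
  }
  fixture_cache$model
}

fixture_model_test_set <- function() {
  fixture_model()
  fixture_cache$model_test
}

# independent brute-force oracle: normalized correlation at every lag,
# written as an explicit double loop (no embed, no matrix algebra)
brute_force_score <- function(window, template) {
  L <- length(template)
  et <- sum(template^2)
  best <- 0
  best_lag <- 0L
  for (k in 0:(length(window) - L)) {
    sub <- window[(k + 1):(k + L)]
    es <- sum(sub^2)
    val <- if (es == 0) 0 else sum(template * sub) / sqrt(et * es)
    if (abs(val) > abs(best)) {
      best <- val
      best_lag <- k
    }
  }
  list(score = best, best_lag = best_lag)
}
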