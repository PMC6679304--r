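# Shared fixtures.  The benchmark used by the end-to-end and sweep tests is
# expensive (full training run), so it is built lazily once per test session
# and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small 2-gesture configuration for fast unit tests
tiny_config <- function(seed = 11) {
  synth_config(
    n_gestures = 2,
    gain_profiles = default_gain_profiles(2, 8),
    seed = seed
  )
}

# a quickly trained model on a small 2-gesture problem with short windows
tiny_model_fixture <- function() {
  memoize("tiny_model", function() {
    cfg <- tiny_config()
    ds <- generate_dataset(cfg, reps_train = 3, reps_test = 4,
                           train_duration_s = 2, test_duration_s = 3)
    wspec <- window_spec(20, 1)
    prepped <- lapply(ds$train$recording, function(rec) {
      preprocess_recording(rec, trim = FALSE)
    })
    ts <- build_training_set(prepped, wspec)
    tc <- train_config(max_epochs = 120, seed = 5)
    model <- train_mlp(init_mlp(ncol(ts$X), 3, tc), ts, config = tc)
    list(config = cfg, dataset = ds, wspec = wspec, model = model,
         training_set = ts)
  })
}

# the full-scale study benchmark: 5 gestures + rest, 5 train / 10 test
# repetitions per gesture, one-hot dominant gain profiles, moderate noise,
# 400 ms windows at 5 ms stride, activation threshold 40
benchmark_fixture <- function() {
  memoize("benchmark", function() {
    cfg <- synth_config(seed = 42)
    ds <- generate_dataset(cfg, reps_train = 5, reps_test = 10,
                           train_duration_s = 2, test_duration_s = 5)
    wspec <- window_spec(80, 1)
    prepped <- lapply(ds$train$recording, function(rec) {
      preprocess_recording(rec, trim = FALSE)
    })
    ts <- build_training_set(prepped, wspec)
    tc <- train_config(learning_rate = 0.1, max_epochs = 250, seed = 1)
    model <- train_mlp(init_mlp(ncol(ts$X), 6, tc), ts, config = tc)
    decisions <- recognize_session(model, ds$test, wspec = wspec, tau = 40)
    list(config = cfg, dataset = ds, wspec = wspec, model = model,
         training_set = ts, decisions = decisions,
         report = evaluate_decisions(decisions, 6))
  })
}
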