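# emgesture

Real-time hand-gesture recognition from multichannel surface
electromyography (sEMG), end to end, in R.

Myoelectric interfaces read the electrical activity of forearm muscles
through a ring of skin electrodes (here: the consumer-armband format — 8
channels, 200 Hz, 8-bit signed samples) and map it to hand gestures.  The
practical constraint is latency: a recognizer that waits for the gesture to
finish is useless for prosthetic or interaction control, so the decision
must be made *during* the movement, conventionally within ~300 ms of onset.

`emgesture` implements a complete streaming recognizer and everything needed
to exercise it without hardware:

1. **Synthetic session generator** — seeded 8-channel recordings with
   relax–gesture–relax structure, gesture-specific per-channel amplitude
   profiles, raised-cosine burst envelopes and known ground-truth onsets.
2. **Preprocessing** — normalization to [−1, 1] by the fixed sensor full
   scale, full-wave rectification, causal 4th-order Butterworth low-pass at
   5 Hz (step-matched initial conditions), and frame-wise spectral
   muscle-activity detection.
3. **Features** — dense sliding windows (400 ms, advanced 5 ms at a time);
   per channel each window carries its *l* envelope samples plus seven
   statistics:

   - mean absolute value `M = (1/N) Σ |s(k)|`
   - root mean square `R = sqrt((1/N) Σ s(k)²)`
   - slope-sign-change statistic `S = Σ |(s(k)−s(k−1))(s(k)−s(k+1))|`
   - waveform length `W = Σ |s(k)−s(k−1)|`
   - Hjorth activity `A = (1/(N−1)) Σ s(k)²`, mobility
     `m = sqrt(VAR(Δs)/VAR(s))` and complexity `C = m(Δs)/m(s)`

   stacked into the `(l+7) × 8` observation matrix `D` and flattened to a
   696-vector for the default window.
4. **Classifier** — a 696–348–6 feedforward sigmoid network (hidden width =
   half the feature length; 6 outputs = 5 gestures + "No-Gesture"), trained
   by full-batch gradient descent on a cross-entropy cost, with stored
   per-feature standardization.
5. **Streaming decision rule** — every classified window votes for its
   label; the first gesture class whose vote count `N_t` reaches the
   activation threshold `τ` (default 40) is emitted, timestamped at the
   right edge of the deciding window.  If nothing reaches `τ`, the decision
   is "No-Gesture".  Response time is signal time from gesture onset.
6. **Evaluation** — confusion matrices with per-class sensitivity/precision,
   response-time summaries, and window-size / threshold sweeps, all as
   tidy tibbles with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Generate a study-like session (5 gestures, 5 training and 10 test
repetitions each), train, and stream-recognize:

```r
library(emgesture)

cfg <- synth_config(seed = 42)
ds  <- generate_dataset(cfg, reps_train = 5, reps_test = 10)

prepped <- lapply(ds$train$recording, preprocess_recording, trim = FALSE)
ts <- build_training_set(prepped, window_spec(80, 1))

tc <- train_config(learning_rate = 0.1, max_epochs = 250, seed = 1)
model <- train_mlp(init_mlp(ncol(ts$X), 6, tc), ts, config = tc)
model
#> <mlp_model> 696-348-6 sigmoid network (bce loss), trained 250 epochs, final cost 0.02544

decisions <- recognize_session(model, ds$test, wspec = window_spec(80, 1), tau = 40)
evaluate_decisions(decisions, n_classes = 6)
#> <eval_report> 50 repetitions, accuracy 100.0%, mean response 487.5 ms, 0 decided No-Gesture
#>      predicted
#> truth 0  1  2  3  4  5
#>     0 0  0  0  0  0  0
#>     1 0 10  0  0  0  0
#>     2 0  0 10  0  0  0
#>     3 0  0  0 10  0  0
#>     4 0  0  0  0 10  0
#>     5 0  0  0  0  0 10
```

Every test repetition is recognized correctly, and the mean response of
~488 ms is well below the mean burst duration (~700 ms): the recognizer
commits while the gesture is still in progress.  (The ~200 ms floor implied
by `τ = 40` votes at a 5 ms stride plus the envelope filter's group delay
account for most of the latency.)  `tidy()` on the report gives per-class
sensitivity, precision and mean response; `autoplot()` draws the confusion
matrix; `sweep_threshold()` and `sweep_window()` reproduce the accuracy /
latency trade-off curves for `τ` and the window size.

A command-line front end covering
`simulate / train / recognize / evaluate / sweep` ships in
`inst/cli/emgesture.R`, driven by a YAML configuration (see
`default_config()`); every command writes a JSON manifest sufficient to
re-run it identically.

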