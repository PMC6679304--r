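---
title: "Streaming sEMG gesture recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming sEMG gesture recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgesture)
```

## The problem

A myoelectric interface reads the electrical activity of forearm muscles
through a ring of surface electrodes and maps it to hand gestures.  For
prosthetics and interaction applications the recognizer must commit *while
the gesture is still being performed* — the conventional budget is about
300 ms from gesture onset — so the pipeline is built around causal
operations and a streaming decision rule rather than whole-recording
classification.

`emgesture` implements that pipeline for the common consumer-armband format:
8 channels, 200 Hz, 8-bit signed samples.  A repetition is one
relax–gesture–relax recording of a single gesture; class 0 is reserved for
rest ("No-Gesture") throughout.

## Preprocessing

Raw integer samples are divided by a fixed full scale (128 for 8-bit signed
data) into $[-1, 1]$, full-wave rectified, and smoothed by a 4th-order
digital Butterworth low-pass with a 5 Hz cut-off.  The result is a
contraction envelope per channel, essentially nonnegative and bounded by 1
up to a small filter overshoot (the package asserts $[-0.05, 1.05]$ and does
not clip).

Two choices here are deliberately conservative for streaming:

* **Fixed full scale.** Normalizing by a per-recording maximum would be
  non-causal and would make train and test scales inconsistent.
* **Causal filtering by default.** The filter is applied as a single forward
  pass with *step-matched initial conditions*: the internal state is
  initialized as if the input had always been at its first sample value,
  which suppresses the startup transient a rectified (nonnegative) signal
  would otherwise excite.  A zero-phase forward–backward mode exists for
  offline use.

**Muscle-activity detection.** The training path must discard the relaxed
head and tail of each repetition.  The envelope is cut into consecutive
64-sample frames (320 ms at 200 Hz, hop = frame); each frame's periodogram
power spectral density is computed per channel, summed across channels, and
the frame is active when its mean density exceeds a threshold in dB relative
to a unit reference density.  The activity interval runs from the first to
the last active frame.  The default threshold of −45 dB was calibrated once
against the synthetic generator's default noise levels, where rest frames
sit near −52 dB and burst frames near −38 dB; both the threshold and the
reference level are exposed as parameters because any absolute dB figure is
meaningless without its reference.  Detection is frame-quantized, so
interval edges are accurate only to ±1 frame; training windows inherit that
fuzziness, which in practice supplies useful transition examples near the
onset.

## Window features

Dense sliding windows (default 80 samples = 400 ms, stride 1 sample = 5 ms)
are cut from the envelope.  Each window contributes, per channel: the $l$
raw envelope samples plus seven statistics — mean absolute value, root mean
square, a slope-sign-change statistic, waveform length, and the Hjorth
activity, mobility and complexity — stacked into an $(l+7) \times 8$ matrix
and flattened channel-major into a vector of length $8(l+7)$ (696 for the
default window).

Two formula-level conventions deserve a note, because the package follows
the defining formulas *as printed* rather than the textbook variants:

* The slope-sign-change statistic is
  $S = \sum_{k=2}^{N-1} |(s_k - s_{k-1})(s_k - s_{k+1})|$, a sum of absolute
  slope products — not the conventional *count* of slope sign changes.  The
  count is available as `ssc_count()` but is not used by default.
* Hjorth activity is the *uncentered* variance
  $\frac{1}{N-1}\sum_k s_k^2$, without mean subtraction.  For rectified
  envelopes the mean is far from zero, so this differs materially from the
  centered variance; the centered form is available via `hjorth(center =
  TRUE)`.  Mobility is $\sqrt{\mathrm{VAR}(\Delta s)/\mathrm{VAR}(s)}$ with
  $\Delta$ the first difference (the standard discretization of the
  derivative), and complexity is the ratio of the derivative's mobility to
  the signal's.  For a pure sinusoid complexity approaches 1 — for a unit
  5 Hz sine sampled at 200 Hz over 2 s it evaluates to 1.0049 — and the
  discrete mobility of a sinusoid of normalized frequency $\omega$
  approaches $2\sin(\omega/2)$.

Degenerate windows: a constant-zero window has zero variance and no
meaningful mobility; the scalar `hjorth()` raises an error there to flag
misuse, while the bulk extractor `extract_features()` maps such windows to
mobility = complexity = 0 so that streaming over silent rest segments cannot
fail.  A nonzero constant window has positive activity, zero mobility and,
by convention, zero complexity.

Training labels: windows fully inside the detected activity interval carry
the repetition's gesture label; windows fully outside carry label 0 when
rest is included; windows straddling a boundary are excluded as ambiguous.

## The classifier

A three-layer feedforward network: input $8(l+7)$, one hidden layer of
$\lfloor \text{input}/2 \rfloor$ sigmoid units, and 6 sigmoid output units
(5 gestures + No-Gesture).  Rest windows are included as a trained class 0
by default, which is what lets the streaming layer tell "no muscle activity"
from "not yet enough evidence".  The cost is the per-example mean of the
summed per-output-unit binary cross-entropy against one-hot targets — the
form consistent with independent sigmoid outputs; a softmax variant is
available behind `loss = "softmax"`.  Averaging over examples (rather than
summing) only rescales the learning rate but makes it independent of the
training-set size.  Optimization is full-batch gradient descent with a fixed
learning rate (default 0.1), seeded uniform initialization in
$[-0.05, 0.05]$, zero biases, and early stopping when the epoch-to-epoch
cost change falls below $10^{-6}$.

**Input standardization.** Each feature column is centered and scaled by its
training-set statistics, which are stored in the model and re-applied at
prediction time.  This is a deliberate design choice: the flattened inputs
mix envelope samples (order $10^{-2}$–$10^{-1}$) with quadratic statistics
(order $10^{-4}$) and dimensionless ratios (order $1$), and the resulting
conditioning is so poor that plain gradient descent stalls near the
rest-majority solution for thousands of epochs.  With standardization the
same optimizer reaches a perfect fit of the synthetic training set within
about 100 epochs at the default learning rate.  Standardization is an
affine reparameterization — the classifier family is unchanged — and can be
disabled with `standardize = FALSE`.

Ties in the output argmax are broken toward the lowest label index.  Models
serialize to a versioned JSON container with weights stored as 17-digit
decimal strings, which round-trips IEEE doubles exactly.

## The streaming decision rule

Each classified window casts a vote for its label.  Per class $t$ a counter
$N_t$ accumulates; the first *gesture* class whose count reaches the
activation threshold $\tau$ (default 40) wins — an "answering racer", which
also resolves ties by arrival order.  If the stream ends with every count
below $\tau$, the decision is class 0, No-Gesture.

Two boundary cases are resolved explicitly:

* **Reach versus exceed.** The decision fires at $N_t \ge \tau$; a strict
  $N_t > \tau$ variant sits behind `strict = TRUE`.
* **Rest votes.** Votes for class 0 are counted but do *not* terminate the
  stream by default.  A test repetition begins with a relaxed arm, so a
  terminal rest count would reach $\tau$ before the gesture even starts and
  the recognizer could never commit to anything else; No-Gesture is instead
  the fallback emitted at stream end.  The literal reading — an accumulated
  rest count also commits, to label 0 — is available via
  `rest_decides = TRUE`.

The decision timestamp is the right edge of the deciding window, the
earliest sample at which that decision is causally computable, and response
time is measured in *signal* time from the true (generator) or detected
onset.  With stride 1 at 200 Hz, $\tau = 40$ imposes a floor of about 195 ms
between the first in-gesture vote and the decision, so reported latencies
below ~200 ms are impossible by construction — a useful sanity check on any
claimed response time.

## The synthetic generator

Real armband data cannot ship with the package, so every stage is exercised
against a seeded synthetic generator that emulates the acquisition protocol:
repetitions of 2 s (training) or 5 s (testing), five gestures, rest before
and after a single burst.  A burst is zero-mean Gaussian carrier noise,
amplitude-modulated by a raised-cosine envelope (default mean duration
0.7 s, ±20% uniform jitter, 0.1 s rise/fall) and scaled per channel by a
gesture-specific gain profile; baseline Gaussian noise (SD 2 raw units) is
present throughout, carrier noise has SD 25 raw units inside the burst, and
samples are quantized by rounding half away from zero and clipping to the
8-bit signed range.  The default gain profiles are one-hot dominant (own
channel 1.0, neighbor 0.5, floor 0.05), making the five classes separable
but overlapping — a deliberate idealization.

What the generator does *not* emulate: motor-unit action-potential shapes
and firing statistics, electrode–skin impedance drift, electrode shift
between sessions, fatigue, crosstalk structure beyond the static gain
matrix, powerline interference, and inter-subject variability.  Passing the
end-to-end tests therefore shows that the pipeline's machinery — envelope
extraction, features, training, vote rule, latency accounting — is correct
and well-calibrated on signals with the assumed burst structure; it does not
certify recognition accuracy on real human data.

## Problem sizes and numerical choices in the test suite

The end-to-end benchmark in the test suite uses 5 gestures + rest, 5
training and 10 test repetitions per gesture, 400 ms windows at stride 1,
$\tau = 40$, and 250 training epochs — sizes chosen so a full run stays in
the minutes range on a single core while still exercising the
study-protocol geometry (the full protocol's 30 test repetitions change
nothing structurally).  Feature extraction over dense windows uses rolling
cumulative sums; it agrees with the per-window definitions to $10^{-8}$
(accumulation order differs) and every statistic is additionally checked
against naive literal-loop oracles at $10^{-9}$ relative tolerance.
Gradients are verified against central differences; the vote rule is
verified exhaustively against a brute-force oracle on all label streams up
to length 8.

## Known limitations

* The muscle-activity detector is frame-quantized and single-threshold; it
  has no hysteresis and will fragment on multi-burst recordings (the
  protocol assumes one gesture per repetition).
* The uncentered Hjorth activity makes mobility and complexity sensitive to
  the envelope's DC level; this is faithful to the defining formulas used
  here but differs from EEG practice.
* Fixed-learning-rate gradient descent has no convergence guarantee on this
  non-convex objective; the defaults are tuned to the synthetic benchmark's
  scale and a real dataset may need a different learning rate or epoch
  budget.
* Response times assume the onset reference is trustworthy; with detected
  (rather than generator-truth) onsets, the ±1-frame detection error
  propagates into the latency estimate.
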