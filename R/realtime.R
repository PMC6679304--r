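#' Per-class vote counter with activation threshold
#'
#' The streaming decision layer counts the label of each classified window
#' per class ("answering racer"): the first gesture class whose count reaches
#' the activation threshold `tau` wins, which also resolves ties by arrival
#' order.  Votes for class 0 (rest / "No-Gesture") are counted but, by
#' default, do not terminate the stream: class 0 is the fallback emitted by
#' [vote_finalize()] when no gesture class reaches the threshold before the
#' stream ends.  Set `rest_decides = TRUE` to let an accumulated rest count
#' also commit the decision (to label 0).
#'
#' The threshold comparison is `count >= tau` by default; `strict = TRUE`
#' uses `count > tau`.
#'
#' @param n_classes number of classes including class 0.
#' @param tau activation threshold (number of votes).
#' @param rest_decides may class 0 commit a decision?
#' @param strict require the count to exceed (rather than reach) `tau`?
#' @return an object of class `vote_state`.
#' @export
#' @examples
#' st <- vote_state(n_classes = 3, tau = 2)
#' st <- vote_update(st, 1, 0)
#' st <- vote_update(st, 1, 1)
#' st$decided_label
vote_state <- function(n_classes = 6, tau = 40, rest_decides = FALSE,
                       strict = FALSE) {
  if (!is_count(n_classes, min = 2)) stop("`n_classes` must be >= 2", call. = FALSE)
  if (!is_count(tau, min = 1)) stop("`tau` must be an integer >= 1", call. = FALSE)
  structure(
    list(
      counts = integer(n_classes),
      tau = as.integer(tau),
      n_classes = as.integer(n_classes),
      windows_seen = 0L,
      decided = FALSE,
      decided_label = NA_integer_,
      decision_window_index = NA_integer_,
      rest_decides = isTRUE(rest_decides),
      strict = isTRUE(strict)
    ),
    class = "vote_state"
  )
}

#' Feed one window label into the vote counter
#'
#' Increments the label's count and commits the decision once an eligible
#' class's count passes the threshold.  Updating an already-decided state is
#' an error; reset with [vote_state()] for the next repetition.
#'
#' @param state a `vote_state`.
#' @param label window label in `0..n_classes-1`.
#' @param window_index index of the window in its stream (recorded as the
#'   decision index when this vote commits).
#' @return the updated `vote_state`.
#' @export
vote_update <- function(state, label, window_index = state$windows_seen) {
  stopifnot(inherits(state, "vote_state"))
  if (state$decided) {
    stop("vote state already decided; reset before further updates", call. = FALSE)
  }
  if (!is_count(label, min = 0) || label >= state$n_classes) {
    stop(sprintf("label must lie in 0..%d", state$n_classes - 1), call. = FALSE)
  }
  state$counts[label + 1] <- state$counts[label + 1] + 1L
  state$windows_seen <- state$windows_seen + 1L
  eligible <- state$rest_decides || label >= 1
  hit <- if (state$strict) state$counts[label + 1] > state$tau
         else state$counts[label + 1] >= state$tau
  if (eligible && hit) {
    state$decided <- TRUE
    state$decided_label <- as.integer(label)
    state$decision_window_index <- as.integer(window_index)
  }
  state
}

#' Final label of a finished stream
#'
#' Returns the committed label, or 0 ("No-Gesture") when no class reached the
#' activation threshold before the stream ended.
#'
#' @param state a `vote_state`.
#' @return an integer class label.
#' @export
vote_finalize <- function(state) {
  stopifnot(inherits(state, "vote_state"))
  if (state$decided) state$decided_label else 0L
}

# fast replay of the vote rule over a whole label stream; returns the decided
# label and 0-based decision index (NA when undecided).  Used by the threshold
# sweep so that cached window labels can be re-scored without re-classifying.
decide_stream <- function(labels, tau, n_classes, rest_decides = FALSE,
                          strict = FALSE) {
  need <- if (strict) tau + 1L else tau
  best_idx <- Inf
  best_label <- NA_integer_
  classes <- if (rest_decides) 0:(n_classes - 1) else seq_len(n_classes - 1)
  for (cl in classes) {
    hits <- which(labels == cl)
    if (length(hits) >= need && hits[need] < best_idx) {
      best_idx <- hits[need]
      best_label <- cl
    }
  }
  if (is.na(best_label)) {
    list(label = 0L, decision_index = NA_integer_)
  } else {
    list(label = as.integer(best_label), decision_index = as.integer(best_idx - 1L))
  }
}

#' Streaming gesture recognition of one recording
#'
#' Causally preprocesses the recording (no trimming), slides dense windows,
#' classifies each window with the trained network, and feeds the labels into
#' the vote counter in window order.  The decision timestamp is the right
#' edge (last sample index + 1) of the deciding window -- the earliest sample
#' at which the decision is computable causally -- and the response time is
#' measured in signal time from the gesture onset.
#'
#' @param model a trained `mlp_model`.
#' @param recording an `semg_recording`.
#' @param fspec a [filter_spec()]; the causal mode preserves streaming
#'   semantics.
#' @param wspec a [window_spec()].
#' @param tau activation threshold.
#' @param onset_reference `"truth"` uses the generator's envelope-support
#'   onset stored in the recording; `"detect"` uses [detect_activity()] on
#'   the envelope.
#' @param full_scale,frame_len,threshold_db preprocessing parameters.
#' @param rest_decides,strict vote-rule variants, see [vote_state()].
#' @return an object of class `gesture_decision`: `label` (0 =
#'   No-Gesture), `decision_sample`, `onset_sample`, `response_ms` (all `NA`
#'   when unavailable), `n_windows`, plus the per-window `window_labels` and
#'   `window_start` streams for caching.
#' @export
stream_recognize <- function(model, recording,
                             fspec = filter_spec(fs = recording$fs),
                             wspec = window_spec(),
                             tau = 40,
                             onset_reference = c("truth", "detect"),
                             full_scale = 128, frame_len = 64,
                             threshold_db = -45,
                             rest_decides = FALSE, strict = FALSE) {
  stopifnot(inherits(model, "mlp_model"), inherits(recording, "semg_recording"))
  onset_reference <- match.arg(onset_reference)
  n <- nrow(recording$samples)
  empty <- function(onset) {
    structure(
      list(label = 0L, decision_sample = NA_integer_, onset_sample = onset,
           response_ms = NA_real_, n_windows = 0L,
           window_labels = integer(0), window_start = integer(0),
           fs = recording$fs, true_label = recording$gesture_label),
      class = "gesture_decision"
    )
  }
  if (n < wspec$length_samples) {
    return(empty(if (onset_reference == "truth") recording$true_onset else NA_integer_))
  }
  sig <- preprocess_recording(recording, spec = fspec, full_scale = full_scale,
                              frame_len = frame_len, threshold_db = threshold_db,
                              trim = FALSE)
  onset <- if (onset_reference == "truth") {
    recording$true_onset
  } else if (sig$has_activity) sig$activity_start else NA_integer_
  fm <- extract_features(sig$envelope, wspec)
  labels <- predict(model, fm)
  state <- vote_state(model$output_dim, tau, rest_decides = rest_decides,
                      strict = strict)
  decision_sample <- NA_integer_
  final <- 0L
  for (i in seq_along(labels)) {
    state <- vote_update(state, labels[i], window_index = i - 1L)
    if (state$decided) {
      decision_sample <- fm$window_start[i] + wspec$length_samples
      break
    }
  }
  final <- vote_finalize(state)
  response_ms <- if (!is.na(decision_sample) && !is.na(onset)) {
    (decision_sample - onset) * 1000 / recording$fs
  } else {
    NA_real_
  }
  structure(
    list(label = as.integer(final),
         decision_sample = as.integer(decision_sample),
         onset_sample = as.integer(onset),
         response_ms = response_ms,
         n_windows = state$windows_seen,
         window_labels = labels,
         window_start = fm$window_start,
         fs = recording$fs,
         true_label = recording$gesture_label),
    class = "gesture_decision"
  )
}

#' @export
print.gesture_decision <- function(x, ...) {
  cat(sprintf(
    "<gesture_decision> label %d (truth %s), decision sample %s, response %s ms\n",
    x$label, as.character(x$true_label), as.character(x$decision_sample),
    if (is.na(x$response_ms)) "NA" else sprintf("%.1f", x$response_ms)
  ))
  invisible(x)
}

#' Recognize every recording of a session
#'
#' Runs [stream_recognize()] over the rows of a session tibble and collects
#' the decisions in tidy form.
#'
#' @param model a trained `mlp_model`.
#' @param session a session tibble with a `recording` list-column (see
#'   [generate_dataset()] / [read_session()]).
#' @param ... passed on to [stream_recognize()].
#' @return a tibble with one row per repetition: `subject`, `gesture` (truth),
#'   `repetition`, `predicted`, `decision_sample`, `onset_sample`,
#'   `response_ms`, `n_windows`.
#' @export
recognize_session <- function(model, session, ...) {
  stopifnot(is.data.frame(session), "recording" %in% names(session))
  decisions <- purrr::map(session$recording, function(rec) {
    stream_recognize(model, rec, ...)
  })
  tibble::tibble(
    subject = session$subject,
    gesture = session$gesture,
    repetition = session$repetition,
    predicted = purrr::map_int(decisions, "label"),
    decision_sample = purrr::map_int(decisions, "decision_sample"),
    onset_sample = purrr::map_int(decisions, "onset_sample"),
    response_ms = purrr::map_dbl(decisions, "response_ms"),
    n_windows = purrr::map_int(decisions, "n_windows")
  )
}
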