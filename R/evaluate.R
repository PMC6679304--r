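#' Confusion matrix and response-time report
#'
#' Builds the repetition-level confusion matrix (rows = truth, columns =
#' prediction, both including class 0 / "No-Gesture"), per-class sensitivity
#' (row-wise recall) and precision (column-wise), the overall accuracy over
#' gesture repetitions, and mean response times.  Repetitions decided as
#' No-Gesture count as errors in the accuracy denominator.  Response times
#' are averaged over correctly recognized repetitions; the average over
#' incorrectly decided ones is reported separately.
#'
#' @param decisions a tibble with columns `gesture` (truth), `predicted` and
#'   `response_ms`, as produced by [recognize_session()].
#' @param n_classes number of classes including class 0.
#' @return an object of class `eval_report`.
#' @export
evaluate_decisions <- function(decisions, n_classes = 6) {
  stopifnot(is.data.frame(decisions), nrow(decisions) > 0,
            all(c("gesture", "predicted") %in% names(decisions)))
  if (any(decisions$gesture < 0) || any(decisions$gesture >= n_classes)) {
    stop(sprintf("truth labels must lie in 0..%d", n_classes - 1), call. = FALSE)
  }
  if (any(decisions$predicted < 0) || any(decisions$predicted >= n_classes)) {
    stop(sprintf("predicted labels must lie in 0..%d", n_classes - 1), call. = FALSE)
  }
  lev <- 0:(n_classes - 1)
  confusion <- table(
    truth = factor(decisions$gesture, levels = lev),
    predicted = factor(decisions$predicted, levels = lev)
  )
  confusion <- unclass(confusion)
  sens <- diag(confusion) / rowSums(confusion)
  sens[rowSums(confusion) == 0] <- NA_real_
  prec <- diag(confusion) / colSums(confusion)
  prec[colSums(confusion) == 0] <- NA_real_
  gesture_rows <- decisions$gesture >= 1
  correct <- decisions$predicted == decisions$gesture
  resp <- if ("response_ms" %in% names(decisions)) decisions$response_ms else
    rep(NA_real_, nrow(decisions))
  by_gesture <- dplyr::summarise(
    dplyr::group_by(decisions[gesture_rows & correct, , drop = FALSE], .data$gesture),
    mean_response_ms = mean(.data$response_ms, na.rm = TRUE),
    n = dplyr::n()
  )
  structure(
    list(
      confusion = confusion,
      per_class_sensitivity = sens,
      per_class_precision = prec,
      overall_accuracy = mean(correct[gesture_rows]),
      mean_response_ms = mean(resp[gesture_rows & correct], na.rm = TRUE),
      mean_response_incorrect_ms = mean(resp[gesture_rows & !correct], na.rm = TRUE),
      response_by_gesture = by_gesture,
      n_no_gesture = sum(gesture_rows & decisions$predicted == 0),
      n = nrow(decisions),
      n_classes = as.integer(n_classes)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d repetitions, accuracy %.1f%%, mean response %.1f ms, %d decided No-Gesture\n",
    x$n, 100 * x$overall_accuracy, x$mean_response_ms, x$n_no_gesture
  ))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.eval_report <- function(x, ...) {
  lev <- 0:(x$n_classes - 1)
  resp <- rep(NA_real_, x$n_classes)
  if (nrow(x$response_by_gesture)) {
    resp[x$response_by_gesture$gesture + 1] <- x$response_by_gesture$mean_response_ms
  }
  tibble::tibble(
    class = lev,
    n = as.integer(rowSums(x$confusion)),
    sensitivity = as.numeric(x$per_class_sensitivity),
    precision = as.numeric(x$per_class_precision),
    mean_response_ms = resp
  )
}

#' @importFrom generics glance
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    overall_accuracy = x$overall_accuracy,
    mean_response_ms = x$mean_response_ms,
    mean_response_incorrect_ms = x$mean_response_incorrect_ms,
    n_no_gesture = x$n_no_gesture
  )
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = sprintf("accuracy %.1f%%", 100 * object$overall_accuracy))
}

train_and_evaluate <- function(train_session, test_session, wspec, tau,
                               fspec, tconfig, full_scale, frame_len,
                               threshold_db, n_classes, include_rest = TRUE) {
  prepped <- purrr::map(train_session$recording, function(rec) {
    preprocess_recording(rec, spec = fspec, full_scale = full_scale,
                         frame_len = frame_len, threshold_db = threshold_db,
                         trim = FALSE)
  })
  ts <- build_training_set(prepped, wspec, include_rest = include_rest)
  model <- init_mlp(ncol(ts$X), n_classes, tconfig)
  model <- train_mlp(model, ts, config = tconfig)
  decisions <- recognize_session(model, test_session,
    fspec = fspec, wspec = wspec, tau = tau, full_scale = full_scale,
    frame_len = frame_len, threshold_db = threshold_db
  )
  list(model = model, decisions = decisions,
       report = evaluate_decisions(decisions, n_classes))
}

#' Accuracy and latency as a function of window size
#'
#' Retrains the classifier and re-evaluates the streaming pipeline for every
#' window length in the grid, holding the activation threshold fixed.  Seeds
#' are fixed by the training configuration, so repeated sweeps are identical.
#'
#' @param train_session,test_session session tibbles with `recording`
#'   list-columns.
#' @param window_ms strictly increasing grid of window sizes in
#'   milliseconds.
#' @param tau activation threshold held fixed across the sweep.
#' @param fs sampling rate used to convert milliseconds to samples.
#' @param stride_samples window stride.
#' @param fspec a [filter_spec()].
#' @param tconfig a [train_config()].
#' @param full_scale,frame_len,threshold_db preprocessing parameters.
#' @param n_classes number of classes including class 0.
#' @return a `sweep_result` tibble with columns `window_ms`,
#'   `length_samples`, `accuracy`, `mean_response_ms`, `n_no_gesture`.
#' @export
sweep_window <- function(train_session, test_session,
                         window_ms = seq(100, 500, by = 50),
                         tau = 40, fs = 200, stride_samples = 1,
                         fspec = filter_spec(fs = fs),
                         tconfig = train_config(),
                         full_scale = 128, frame_len = 64, threshold_db = -45,
                         n_classes = 6) {
  if (is.unsorted(window_ms, strictly = TRUE)) {
    stop("`window_ms` must be strictly increasing", call. = FALSE)
  }
  rows <- purrr::map(window_ms, function(wms) {
    l <- round(wms * fs / 1000)
    res <- train_and_evaluate(
      train_session, test_session,
      wspec = window_spec(l, stride_samples), tau = tau, fspec = fspec,
      tconfig = tconfig, full_scale = full_scale, frame_len = frame_len,
      threshold_db = threshold_db, n_classes = n_classes
    )
    tibble::tibble(
      window_ms = wms, length_samples = l,
      accuracy = res$report$overall_accuracy,
      mean_response_ms = res$report$mean_response_ms,
      n_no_gesture = res$report$n_no_gesture
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "parameter") <- "window_ms"
  out
}

#' Accuracy and latency as a function of the activation threshold
#'
#' Classifies every window of every test recording once, caches the label
#' streams, and replays only the vote rule for each threshold in the grid.
#' Larger thresholds can only delay decisions, so per-repetition latency is
#' nondecreasing in `tau`; once `tau` exceeds the number of gesture-labeled
#' windows of a repetition it falls back to No-Gesture.
#'
#' @param model a trained `mlp_model`.
#' @param test_session session tibble with a `recording` list-column.
#' @param taus strictly increasing grid of activation thresholds.
#' @param wspec a [window_spec()].
#' @param fspec a [filter_spec()].
#' @param full_scale,frame_len,threshold_db preprocessing parameters.
#' @param rest_decides,strict vote-rule variants, see [vote_state()].
#' @return a `sweep_result` tibble with columns `tau`, `accuracy`,
#'   `mean_response_ms`, `n_no_gesture`.
#' @export
sweep_threshold <- function(model, test_session, taus = seq(10, 100, by = 10),
                            wspec = window_spec(),
                            fspec = NULL,
                            full_scale = 128, frame_len = 64, threshold_db = -45,
                            rest_decides = FALSE, strict = FALSE) {
  if (is.unsorted(taus, strictly = TRUE)) {
    stop("`taus` must be strictly increasing", call. = FALSE)
  }
  if (any(taus < 1)) stop("thresholds must be >= 1", call. = FALSE)
  streams <- purrr::map(test_session$recording, function(rec) {
    dec <- stream_recognize(
      model, rec,
      fspec = if (is.null(fspec)) filter_spec(fs = rec$fs) else fspec,
      wspec = wspec, tau = .Machine$integer.max, # never decides: we only want labels
      onset_reference = "truth", full_scale = full_scale,
      frame_len = frame_len, threshold_db = threshold_db,
      rest_decides = rest_decides, strict = strict
    )
    list(labels = dec$window_labels, window_start = dec$window_start,
         onset = dec$onset_sample, fs = dec$fs, truth = rec$gesture_label)
  })
  rows <- purrr::map(taus, function(tau) {
    decs <- purrr::map(streams, function(s) {
      d <- decide_stream(s$labels, tau, model$output_dim,
                         rest_decides = rest_decides, strict = strict)
      resp <- if (!is.na(d$decision_index) && !is.na(s$onset)) {
        (s$window_start[d$decision_index + 1] + wspec$length_samples - s$onset) *
          1000 / s$fs
      } else {
        NA_real_
      }
      tibble::tibble(gesture = s$truth, predicted = d$label, response_ms = resp)
    })
    rep_df <- dplyr::bind_rows(decs)
    report <- evaluate_decisions(rep_df, n_classes = model$output_dim)
    tibble::tibble(
      tau = tau,
      accuracy = report$overall_accuracy,
      mean_response_ms = report$mean_response_ms,
      n_no_gesture = report$n_no_gesture
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "parameter") <- "tau"
  out
}

#' @export
autoplot.sweep_result <- function(object, metric = c("accuracy", "mean_response_ms"),
                                  ...) {
  metric <- match.arg(metric)
  param <- attr(object, "parameter")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[param]], y = .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = param, y = metric)
}
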