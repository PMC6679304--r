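#' Sliding-window specification
#'
#' The dense sliding window used for feature extraction: 80 samples (400 ms
#' at 200 Hz) advanced by one sample (5 ms) per step.  Windows need at least
#' 3 samples so that the slope-sign-change statistic and the Hjorth
#' derivatives are defined.
#'
#' @param length_samples window length in samples.
#' @param stride_samples stride between consecutive window starts, in samples.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length_samples = 80, stride_samples = 1) {
  stop_if_not_count(length_samples, "length_samples", min = 3)
  stop_if_not_count(stride_samples, "stride_samples", min = 1)
  structure(
    list(length_samples = as.integer(length_samples),
         stride_samples = as.integer(stride_samples)),
    class = "window_spec"
  )
}

# canonical per-channel feature order used throughout the package
feature_names <- function() {
  c("mav", "rms", "ssc", "wl", "activity", "mobility", "complexity")
}

#' Time-domain features of one window channel
#'
#' Classical sEMG window statistics.  With `s(k)` the `k`-th sample of the
#' window and `N` its length:
#'
#' * `mav(s) = (1/N) * sum |s(k)|` -- mean absolute value;
#' * `rms(s) = sqrt((1/N) * sum s(k)^2)` -- root mean square;
#' * `ssc(s) = sum_{k=2}^{N-1} |(s(k)-s(k-1)) * (s(k)-s(k+1))|` -- the
#'   slope-sign-change statistic implemented literally as a sum of absolute
#'   slope products (see Details);
#' * `wl(s)  = sum_{k=2}^{N} |s(k)-s(k-1)|` -- waveform length.
#'
#' @details `ssc()` is a sum of absolute products of adjacent slopes, not an
#' indicator count, matching the defining formula as printed rather than the
#' conventional count of slope sign changes.  The conventional count is
#' available as [ssc_count()].
#'
#' @param x numeric vector, one channel of one window.
#' @return a single numeric value.
#' @export
mav <- function(x) {
  if (!length(x)) stop("empty window", call. = FALSE)
  sum(abs(x)) / length(x)
}

#' @rdname mav
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty window", call. = FALSE)
  sqrt(sum(x^2) / length(x))
}

#' @rdname mav
#' @export
ssc <- function(x) {
  if (length(x) < 3) stop("ssc needs at least 3 samples", call. = FALSE)
  d <- diff(x)
  sum(abs(d[-length(d)] * d[-1]))
}

#' Count of slope sign changes
#'
#' The conventional indicator-count alternative to [ssc()]: the number of
#' interior samples at which the slope changes sign.
#'
#' @param x numeric vector with at least 3 samples.
#' @return an integer count.
#' @export
ssc_count <- function(x) {
  if (length(x) < 3) stop("ssc_count needs at least 3 samples", call. = FALSE)
  d <- diff(x)
  sum(d[-length(d)] * d[-1] < 0)
}

#' @rdname mav
#' @export
wl <- function(x) {
  if (length(x) < 2) stop("wl needs at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

# the uncentered variance used by the Hjorth parameters: (1/(N-1)) sum s^2
hjorth_var <- function(x, center = FALSE) {
  if (center) x <- x - mean(x)
  sum(x^2) / (length(x) - 1)
}

#' Hjorth parameters of one window channel
#'
#' Activity, mobility and complexity of a time series.  Activity is the
#' (uncentered) variance `(1/(N-1)) * sum s(k)^2`; mobility is
#' `sqrt(VAR(ds)/VAR(s))` with `ds` the first difference; complexity is the
#' ratio of the mobility of the derivative to the mobility of the signal,
#' which approaches 1 for a pure sine wave.  Variances are computed without
#' mean subtraction by default, matching the defining activity formula as
#' printed; set `center = TRUE` for the conventional centered variant.
#'
#' A constant-zero window (zero variance) is degenerate and raises an error.
#' When the first difference has zero variance but the signal does not (a
#' nonzero constant window), complexity is 0 by convention.
#'
#' @param x numeric vector with at least 3 samples.
#' @param center subtract the mean inside the variances?
#' @return a named list with `activity`, `mobility`, `complexity`.
#' @export
#' @examples
#' s <- sin(2 * pi * 5 * (0:399) / 200)
#' hjorth(s)$complexity # close to 1 for a pure sine
hjorth <- function(x, center = FALSE) {
  if (length(x) < 3) stop("hjorth needs at least 3 samples", call. = FALSE)
  v0 <- hjorth_var(x, center)
  if (v0 == 0) stop("degenerate (constant-zero variance) window", call. = FALSE)
  d1 <- diff(x)
  v1 <- hjorth_var(d1, center)
  mobility <- sqrt(v1 / v0)
  if (v1 == 0) {
    return(list(activity = v0, mobility = 0, complexity = 0))
  }
  d2 <- diff(d1)
  v2 <- hjorth_var(d2, center)
  mobility_d <- sqrt(v2 / v1)
  list(activity = v0, mobility = mobility, complexity = mobility_d / mobility)
}

#' Feature matrix of one window
#'
#' Stacks the raw window samples with the seven per-channel features into the
#' classifier observation `D`: rows `1..l` are the window's envelope samples,
#' rows `l+1..l+7` are mean absolute value, root mean square, the
#' slope-sign-change statistic, waveform length, and the Hjorth activity,
#' mobility and complexity, one column per channel.  `flat` is the
#' channel-major flattening of `D` (all rows of channel 1, then channel 2,
#' and so on), of length `n_channels * (l + 7)`.
#'
#' @param window numeric `l x n_channels` matrix, `l >= 3`.
#' @param window_start 0-based start index of the window in its source
#'   signal (metadata).
#' @param label class label of the window, or `NA`.
#' @return an object of class `feature_window` with elements `D`, `flat`,
#'   `window_start`, `label`.
#' @export
window_features <- function(window, window_start = NA_integer_, label = NA_integer_) {
  if (!is.matrix(window)) window <- matrix(window, ncol = 1)
  l <- nrow(window)
  if (l < 3) stop("window must have at least 3 rows", call. = FALSE)
  feats <- apply(window, 2, function(ch) {
    h <- hjorth(ch)
    c(mav(ch), rms(ch), ssc(ch), wl(ch), h$activity, h$mobility, h$complexity)
  })
  feats <- matrix(feats, nrow = 7)
  D <- rbind(window, feats)
  rownames(D) <- c(paste0("s", seq_len(l)), feature_names())
  structure(
    list(D = D, flat = as.vector(D), window_start = window_start, label = label),
    class = "feature_window"
  )
}

#' Enumerate dense sliding windows
#'
#' Yields windows `[i, i + l)` for `i = 0, stride, 2*stride, ...` while
#' `i + l` does not exceed the signal length; the number of windows is
#' `floor((length - l)/stride) + 1`.  A signal shorter than one window yields
#' an empty result, not an error.
#'
#' @param envelope numeric matrix (samples x channels).
#' @param spec a [window_spec()].
#' @return a tibble with columns `window_start` (0-based) and `window`
#'   (list-column of `l x n_channels` matrices).
#' @export
sliding_windows <- function(envelope, spec = window_spec()) {
  if (!is.matrix(envelope)) envelope <- matrix(envelope, ncol = 1)
  l <- spec$length_samples
  n <- nrow(envelope)
  if (n < l) {
    return(tibble::tibble(window_start = integer(0), window = list()))
  }
  starts <- seq.int(0L, n - l, by = spec$stride_samples)
  tibble::tibble(
    window_start = as.integer(starts),
    window = purrr::map(starts, function(i) envelope[(i + 1):(i + l), , drop = FALSE])
  )
}

#' Extract the feature matrix of every sliding window
#'
#' Vectorized bulk version of [window_features()] over all dense windows of a
#' signal, using rolling cumulative sums.  Row `i` of `X` is the flattened
#' feature vector of the window starting at `window_start[i]`; values agree
#' with [window_features()] up to floating-point accumulation order.
#' Degenerate (constant) windows, which [hjorth()] rejects for a single
#' window, are mapped to mobility and complexity 0 here so that bulk
#' extraction over rest segments cannot fail.
#'
#' @param envelope numeric matrix (samples x channels).
#' @param spec a [window_spec()].
#' @return an object of class `feature_matrix`: a list with `X` (numeric
#'   `n_windows x n_channels*(l+7)` matrix), `window_start` (0-based integer
#'   vector) and `spec`.
#' @export
extract_features <- function(envelope, spec = window_spec()) {
  if (!is.matrix(envelope)) envelope <- matrix(envelope, ncol = 1)
  l <- spec$length_samples
  n <- nrow(envelope)
  nc <- ncol(envelope)
  if (n < l) {
    return(structure(
      list(X = matrix(numeric(0), 0, nc * (l + 7)), window_start = integer(0), spec = spec),
      class = "feature_matrix"
    ))
  }
  starts <- seq.int(0L, n - l, by = spec$stride_samples)
  keep <- starts + 1L # 1-based index into the stride-1 rolling vectors
  nw <- length(starts)
  X <- matrix(0, nw, nc * (l + 7))
  widx <- outer(starts, seq_len(l), "+") # nw x l matrix of 1-based row indices
  for (ch in seq_len(nc)) {
    x <- envelope[, ch]
    d <- diff(x)
    d2 <- diff(d)
    p <- abs(d[-length(d)] * d[-1])
    s_abs <- rollsum(abs(x), l)[keep]
    s_sq <- rollsum(x^2, l)[keep]
    wl_v <- rollsum(abs(d), l - 1)[keep]
    v1 <- rollsum(d^2, l - 1)[keep] / (l - 2)
    ssc_v <- rollsum(p, l - 2)[keep]
    v2 <- rollsum(d2^2, l - 2)[keep] / (l - 3)
    v0 <- s_sq / (l - 1)
    mob <- sqrt(v1 / v0)
    mob[!is.finite(mob)] <- 0
    mob_d <- sqrt(v2 / v1)
    mob_d[!is.finite(mob_d)] <- 0
    cplx <- mob_d / mob
    cplx[!is.finite(cplx)] <- 0
    W <- matrix(x[widx], nw, l)
    X[, ((ch - 1) * (l + 7) + 1):(ch * (l + 7))] <-
      cbind(W, s_abs / l, sqrt(s_sq / l), ssc_v, wl_v, v0, mob, cplx)
  }
  structure(
    list(X = X, window_start = as.integer(starts), spec = spec),
    class = "feature_matrix"
  )
}

#' Build a labeled training set from preprocessed repetitions
#'
#' Slides dense windows over each untrimmed envelope and labels them by the
#' repetition's gesture and its detected activity interval: windows fully
#' inside the interval receive the gesture label; with `include_rest`,
#' windows fully outside receive label 0 (rest / "No-Gesture"); windows that
#' straddle an activity boundary are excluded as ambiguous.  Envelopes that
#' were already trimmed to their activity interval contribute every window
#' under the gesture label (no rest windows are available from them).
#'
#' @param signals a list of `preprocessed_signal` objects, or a data frame
#'   with a `signal` list-column holding them.
#' @param spec a [window_spec()].
#' @param include_rest label out-of-activity windows as class 0?
#' @return an object of class `training_set`: a list with `X` (feature
#'   matrix, one flattened window per row), `y` (integer labels, 0 = rest),
#'   `window_start` and `source` (repetition index of each row).
#' @export
build_training_set <- function(signals, spec = window_spec(), include_rest = TRUE) {
  if (is.data.frame(signals)) signals <- signals$signal
  stopifnot(length(signals) > 0)
  l <- spec$length_samples
  xs <- list()
  ys <- list()
  ws <- list()
  src <- list()
  for (i in seq_along(signals)) {
    sig <- signals[[i]]
    stopifnot(inherits(sig, "preprocessed_signal"))
    label <- sig$gesture_label %||% NA_integer_
    fm <- extract_features(sig$envelope, spec)
    if (!nrow(fm$X)) next
    if (sig$trimmed) {
      if (is.na(label) || label < 1) next
      sel <- seq_len(nrow(fm$X))
      lab <- rep(label, length(sel))
    } else if (sig$has_activity) {
      inside <- fm$window_start >= sig$activity_start &
        (fm$window_start + l) <= sig$activity_end
      outside <- (fm$window_start + l) <= sig$activity_start |
        fm$window_start >= sig$activity_end
      sel <- which(inside | (include_rest & outside))
      lab <- ifelse(inside[sel], label, 0L)
    } else {
      if (!is.na(label) && label >= 1) {
        warning(sprintf(
          "repetition %d (gesture %d): no muscle activity detected; skipped", i, label
        ), call. = FALSE)
        next
      }
      if (!include_rest) next
      sel <- seq_len(nrow(fm$X))
      lab <- rep(0L, length(sel))
    }
    if (!length(sel)) next
    xs[[length(xs) + 1]] <- fm$X[sel, , drop = FALSE]
    ys[[length(ys) + 1]] <- as.integer(lab)
    ws[[length(ws) + 1]] <- fm$window_start[sel]
    src[[length(src) + 1]] <- rep(i, length(sel))
  }
  if (!length(xs)) stop("no training windows could be produced", call. = FALSE)
  structure(
    list(
      X = do.call(rbind, xs),
      y = unlist(ys),
      window_start = unlist(ws),
      source = unlist(src),
      spec = spec
    ),
    class = "training_set"
  )
}

#' Persist a feature matrix as delimited text with a JSON sidecar
#'
#' The sidecar records the window length, stride, sampling rate, flattening
#' order and per-channel feature order, so the matrix can be re-read without
#' ambiguity.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param path path of the delimited text file; the sidecar is written to
#'   `<path>.json`.
#' @param fs sampling rate recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, fs = 200) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.table(cbind(fm$window_start, fm$X), path,
    row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  meta <- list(
    length_samples = fm$spec$length_samples,
    stride_samples = fm$spec$stride_samples,
    fs = fs,
    flattening = "channel-major",
    feature_order = feature_names(),
    n_windows = nrow(fm$X),
    n_columns = ncol(fm$X)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
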