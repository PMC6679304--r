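#' Default per-gesture channel gain profiles
#'
#' Builds one amplitude-gain row per gesture over the armband channels.  Each
#' gesture is dominated by its own electrode (gain 1), spills over onto the
#' next electrode around the band (gain 0.5), and leaves a small co-activation
#' floor (gain 0.05) on the remaining channels, so the profiles are pairwise
#' distinct and one-hot dominant.
#'
#' @param n_gestures number of gesture classes (excluding rest).
#' @param n_channels number of electrode channels.
#' @return a numeric `n_gestures x n_channels` matrix with entries in `[0, 1]`.
#' @export
#' @examples
#' default_gain_profiles(5, 8)
default_gain_profiles <- function(n_gestures = 5, n_channels = 8) {
  stop_if_not_count(n_gestures, "n_gestures")
  stop_if_not_count(n_channels, "n_channels")
  if (n_gestures > n_channels) {
    stop("need at least as many channels as gestures for one-hot dominant profiles",
         call. = FALSE)
  }
  g <- matrix(0.05, n_gestures, n_channels)
  for (i in seq_len(n_gestures)) {
    g[i, i] <- 1
    g[i, (i %% n_channels) + 1] <- 0.5
  }
  g
}

#' Configuration of the synthetic sEMG generator
#'
#' Describes the armband and recording-protocol conditions the generator
#' emulates: an 8-channel sensor sampling at 200 Hz with 8-bit signed
#' resolution, rest-state baseline noise, and gesture bursts of roughly
#' 0.5--2 s whose per-channel amplitudes follow a gesture-specific gain
#' profile.  Each repetition has the relax--gesture--relax structure.
#'
#' The carrier model is zero-mean white noise, amplitude-modulated by a
#' raised-cosine envelope and scaled per channel; no physiological motor-unit
#' firing model is attempted.  Ground-truth onset/offset are defined by the
#' support of the modulation envelope, which gives an unambiguous reference
#' for response-time measurement.
#'
#' @param n_channels number of electrode channels.
#' @param fs sampling rate in Hz.
#' @param n_gestures number of gesture classes (labels `1..n_gestures`; label
#'   0 is reserved for rest / "No-Gesture").
#' @param gain_profiles `n_gestures x n_channels` matrix of per-channel
#'   amplitude gains in `[0, 1]`; rows must be pairwise distinct.
#' @param burst_duration_s mean gesture-burst duration in seconds.
#' @param burst_jitter fraction by which the burst duration varies uniformly
#'   around its mean (0.2 means +/-20%).
#' @param envelope_rise_s rise/fall time of the raised-cosine burst envelope,
#'   in seconds.
#' @param baseline_noise_std standard deviation of the rest-state noise, in
#'   raw sensor units.
#' @param burst_noise_std standard deviation of the active-state carrier
#'   noise before envelope modulation, in raw sensor units.
#' @param quantization_bits signed-integer resolution of the sensor.
#' @param seed integer seed driving all generation from this configuration.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' rec <- generate_repetition(cfg, gesture = 1, duration_s = 2)
#' dim(rec$samples)
synth_config <- function(n_channels = 8,
                         fs = 200,
                         n_gestures = 5,
                         gain_profiles = default_gain_profiles(n_gestures, n_channels),
                         burst_duration_s = 0.7,
                         burst_jitter = 0.2,
                         envelope_rise_s = 0.1,
                         baseline_noise_std = 2,
                         burst_noise_std = 25,
                         quantization_bits = 8,
                         seed = 1L) {
  stop_if_not_count(n_channels, "n_channels")
  stop_if_not_count(fs, "fs")
  stop_if_not_count(n_gestures, "n_gestures")
  stop_if_not_count(quantization_bits, "quantization_bits", min = 2)
  gain_profiles <- as.matrix(gain_profiles)
  if (!identical(dim(gain_profiles), c(n_gestures, n_channels)) &&
      !identical(dim(gain_profiles), as.integer(c(n_gestures, n_channels)))) {
    stop("`gain_profiles` must be an n_gestures x n_channels matrix", call. = FALSE)
  }
  if (any(gain_profiles < 0) || any(gain_profiles > 1)) {
    stop("`gain_profiles` entries must lie in [0, 1]", call. = FALSE)
  }
  if (n_gestures > 1 && anyDuplicated(gain_profiles) > 0) {
    stop("each pair of gesture gain profiles must differ in at least one channel",
         call. = FALSE)
  }
  if (burst_duration_s <= 0 || burst_jitter < 0 || burst_jitter >= 1 ||
      envelope_rise_s < 0 || baseline_noise_std < 0 || burst_noise_std < 0) {
    stop("noise/timing parameters must be nonnegative (jitter in [0, 1))", call. = FALSE)
  }
  structure(
    list(
      n_channels = as.integer(n_channels),
      fs = as.integer(fs),
      n_gestures = as.integer(n_gestures),
      gain_profiles = gain_profiles,
      burst_duration_s = burst_duration_s,
      burst_jitter = burst_jitter,
      envelope_rise_s = envelope_rise_s,
      baseline_noise_std = baseline_noise_std,
      burst_noise_std = burst_noise_std,
      quantization_bits = as.integer(quantization_bits),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d channels @ %d Hz, %d gestures, burst %.2fs +/-%d%%, noise %.3g/%.3g, %d-bit\n",
    x$n_channels, x$fs, x$n_gestures, x$burst_duration_s,
    round(100 * x$burst_jitter), x$baseline_noise_std, x$burst_noise_std,
    x$quantization_bits
  ))
  invisible(x)
}

# round half away from zero, clip to the signed range of `bits`
quantize_samples <- function(x, bits) {
  lo <- -2^(bits - 1)
  hi <- 2^(bits - 1) - 1
  q <- sign(x) * floor(abs(x) + 0.5)
  matrix(as.integer(pmin(pmax(q, lo), hi)), nrow(x), ncol(x))
}

# raised-cosine on/plateau/off envelope over `len` samples
raised_cosine_envelope <- function(len, rise) {
  env <- rep(1, len)
  if (rise > 0) {
    k <- seq_len(min(rise, len))
    env[k] <- (1 - cos(pi * k / rise)) / 2
    env[len - k + 1] <- pmin(env[len - k + 1], (1 - cos(pi * k / rise)) / 2)
  }
  env
}

#' Generate one synthetic sEMG repetition
#'
#' Produces a single relax--gesture--relax recording: baseline noise outside
#' the burst and, inside it, baseline noise plus zero-mean carrier noise
#' amplitude-modulated by a raised-cosine envelope and scaled per channel by
#' the gesture's gain profile.  Samples are quantized to the signed integer
#' range implied by `quantization_bits`.  All sample indices are 0-based and
#' the burst interval `[true_onset, true_offset)` is half-open.
#'
#' @param config a [synth_config()].
#' @param gesture gesture label in `1..n_gestures`, or 0 for a pure-rest
#'   recording (no burst).
#' @param duration_s total recording duration in seconds.
#' @param seed integer seed; defaults to the configuration seed.  Two calls
#'   with the same seed return identical recordings.
#' @param subject_id subject identifier stored in the recording.
#' @param repetition repetition index stored in the recording.
#' @return an object of class `semg_recording` with elements `samples`
#'   (integer `N x n_channels` matrix), `fs`, `subject_id`, `gesture_label`,
#'   `repetition_index`, `true_onset`, `true_offset`.
#' @export
generate_repetition <- function(config, gesture, duration_s,
                                seed = config$seed,
                                subject_id = "S1", repetition = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_count(gesture, min = 0) || gesture > config$n_gestures) {
    stop(sprintf("`gesture` must be 0 (rest) or in 1..%d", config$n_gestures),
         call. = FALSE)
  }
  n <- round(duration_s * config$fs)
  if (n < 1) stop("`duration_s` must cover at least one sample", call. = FALSE)

  gen <- function() {
    nc <- config$n_channels
    x <- matrix(stats::rnorm(n * nc, 0, config$baseline_noise_std), n, nc)
    onset <- NA_integer_
    offset <- NA_integer_
    if (gesture >= 1) {
      jit <- if (config$burst_jitter > 0) stats::runif(1, -config$burst_jitter, config$burst_jitter) else 0
      burst_len <- round(config$burst_duration_s * (1 + jit) * config$fs)
      rise <- round(config$envelope_rise_s * config$fs)
      if (burst_len + 2 * rise > n) {
        stop(sprintf(
          "infeasible timing: burst of %d samples plus %d-sample margins does not fit in %d samples",
          burst_len, rise, n
        ), call. = FALSE)
      }
      onset <- as.integer(sample(seq.int(rise, n - burst_len - rise), 1))
      offset <- onset + as.integer(burst_len)
      env <- raised_cosine_envelope(burst_len, rise)
      carrier <- matrix(stats::rnorm(burst_len * nc, 0, config$burst_noise_std), burst_len, nc)
      gains <- matrix(config$gain_profiles[gesture, ], burst_len, nc, byrow = TRUE)
      x[(onset + 1):offset, ] <- x[(onset + 1):offset, ] + carrier * env * gains
    }
    structure(
      list(
        samples = quantize_samples(x, config$quantization_bits),
        fs = config$fs,
        subject_id = subject_id,
        gesture_label = as.integer(gesture),
        repetition_index = as.integer(repetition),
        true_onset = onset,
        true_offset = offset
      ),
      class = "semg_recording"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @export
print.semg_recording <- function(x, ...) {
  burst <- if (is.na(x$true_onset)) "rest (no burst)" else
    sprintf("burst [%d, %d)", x$true_onset, x$true_offset)
  cat(sprintf(
    "<semg_recording> %d x %d @ %d Hz, subject %s, gesture %d rep %d, %s\n",
    nrow(x$samples), ncol(x$samples), x$fs, x$subject_id,
    x$gesture_label, x$repetition_index, burst
  ))
  invisible(x)
}

#' Generate a labeled train/test session
#'
#' Emulates the acquisition protocol of an armband study: short repetitions
#' for training and longer repetitions for testing, several per gesture, each
#' with the relax--gesture--relax structure.  Per-repetition seeds are derived
#' deterministically from the configuration seed, so a fixed seed yields an
#' identical session.
#'
#' @param config a [synth_config()].
#' @param reps_train,reps_test repetitions per gesture in each split.
#' @param train_duration_s,test_duration_s repetition length per split, in
#'   seconds.
#' @param subject_id subject identifier.
#' @return a list with tibbles `train` and `test`; each row holds one
#'   `semg_recording` in the `recording` list-column alongside `subject`,
#'   `gesture`, `repetition`, `onset`, `offset`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(seed = 7), reps_train = 1, reps_test = 1)
#' nrow(ds$train)
generate_dataset <- function(config,
                             reps_train = 5,
                             reps_test = 30,
                             train_duration_s = 2,
                             test_duration_s = 5,
                             subject_id = "S1") {
  stopifnot(inherits(config, "synth_config"))
  stop_if_not_count(reps_train, "reps_train")
  stop_if_not_count(reps_test, "reps_test")
  one_split <- function(reps, duration_s, offset) {
    rows <- list()
    k <- 0L
    for (g in seq_len(config$n_gestures)) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        rec <- generate_repetition(
          config, g, duration_s,
          seed = derive_seed(config$seed %||% 0L, offset + k),
          subject_id = subject_id, repetition = r
        )
        rows[[k]] <- tibble::tibble(
          recording = list(rec), subject = subject_id, gesture = g,
          repetition = r, onset = rec$true_onset, offset = rec$true_offset
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  list(
    train = one_split(reps_train, train_duration_s, 0L),
    test = one_split(reps_test, test_duration_s, 100000L)
  )
}

#' Write / read one recording as delimited text
#'
#' The on-disk format is one row per sample and one integer column per
#' channel, preceded by a single comment header line
#' `# fs=<hz> subject=<id> gesture=<g> rep=<k> onset=<i> offset=<j>`
#' (onset/offset are 0-based sample indices, `NA` for pure rest).
#'
#' @param recording an `semg_recording`.
#' @param path file path to write to / read from.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `semg_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "semg_recording"))
  header <- sprintf(
    "# fs=%d subject=%s gesture=%d rep=%d onset=%s offset=%s",
    recording$fs, recording$subject_id, recording$gesture_label,
    recording$repetition_index,
    as.character(recording$true_onset), as.character(recording$true_offset)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(recording$samples, con,
    row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) {
    stop(sprintf("'%s' has no '# fs=... ' header line", path), call. = FALSE)
  }
  grab <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "=[^ ]+"), header))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  to_int <- function(s) if (is.na(s) || s == "NA") NA_integer_ else as.integer(s)
  samples <- as.matrix(utils::read.table(path, comment.char = "#", sep = "\t"))
  dimnames(samples) <- NULL
  structure(
    list(
      samples = matrix(as.integer(samples), nrow(samples), ncol(samples)),
      fs = to_int(grab("fs")),
      subject_id = grab("subject"),
      gesture_label = to_int(grab("gesture")),
      repetition_index = to_int(grab("rep")),
      true_onset = to_int(grab("onset")),
      true_offset = to_int(grab("offset"))
    ),
    class = "semg_recording"
  )
}

#' Write / read a session directory
#'
#' A session is a directory with one delimited text file per repetition plus a
#' tab-separated `manifest.tsv` listing `file`, `subject`, `gesture`,
#' `repetition`, `onset`, `offset`.
#'
#' @param session a tibble as produced by [generate_dataset()] (one split).
#' @param dir directory to create/populate or to read.
#' @return `write_session()` returns `dir` invisibly; `read_session()` returns
#'   a session tibble with a `recording` list-column.
#' @export
write_session <- function(session, dir) {
  stopifnot(is.data.frame(session), "recording" %in% names(session))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("rec_g%d_r%03d.txt", session$gesture, session$repetition)
  purrr::walk2(session$recording, files, function(rec, f) {
    write_recording(rec, file.path(dir, f))
  })
  manifest <- tibble::tibble(
    file = files, subject = session$subject, gesture = session$gesture,
    repetition = session$repetition, onset = session$onset, offset = session$offset
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
    row.names = FALSE, sep = "\t", quote = FALSE
  )
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) {
    stop(sprintf("no manifest.tsv found in '%s'", dir), call. = FALSE)
  }
  manifest <- utils::read.table(mpath, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  recs <- purrr::map(manifest$file, function(f) read_recording(file.path(dir, f)))
  tibble::tibble(
    recording = recs,
    subject = manifest$subject,
    gesture = manifest$gesture,
    repetition = manifest$repetition,
    onset = manifest$onset,
    offset = manifest$offset,
    file = manifest$file
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.semg_recording <- function(object, ...) {
  n <- nrow(object$samples)
  df <- tibble::tibble(
    t = rep((seq_len(n) - 1) / object$fs, ncol(object$samples)),
    value = as.vector(object$samples),
    channel = factor(rep(seq_len(ncol(object$samples)), each = n))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 2) +
    ggplot2::labs(x = "time [s]", y = "raw amplitude",
                  title = sprintf("gesture %d", object$gesture_label))
  if (!is.na(object$true_onset)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(object$true_onset, object$true_offset) / object$fs,
      linetype = "dashed", colour = "red"
    )
  }
  p
}
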