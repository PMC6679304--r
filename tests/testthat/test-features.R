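test_that("window statistics reproduce their defining formulas on known cases", {
  expect_equal(mav(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(mav(rep(0, 5)), 0)
  expect_equal(mav(c(-1, 1, -1, 1)), 1)
  expect_error(mav(numeric(0)), "empty")

  expect_equal(rms(rep(0.3, 4)), 0.3)
  expect_equal(rms(c(3, 4)), sqrt(25 / 2))
  expect_equal(rms(rep(0, 4)), 0)

  expect_equal(ssc(c(1, 3, 2, 4)), 4) # |2*1| + |-1*-2|
  expect_equal(ssc(c(0, 1, 2, 3)), 2) # |1*-1| + |1*-1|
  expect_equal(ssc(rep(5, 6)), 0)
  expect_error(ssc(c(1, 2)), "3 samples")
  # the conventional count differs on a monotone ramp
  expect_equal(ssc_count(c(0, 1, 2, 3)), 0)
  expect_equal(ssc_count(c(1, 3, 2, 4)), 2)

  expect_equal(wl(c(0, 1, 0.5)), 1.5)
  expect_equal(wl(rep(2, 5)), 0)
  expect_equal(wl(c(0, -1, 1)), 3)
  expect_error(wl(1), "2 samples")
})

test_that("Hjorth parameters behave like their spectral interpretations", {
  s <- sin(2 * pi * 5 * (0:399) / 200)
  h <- hjorth(s)
  expect_equal(h$complexity, 1, tolerance = 0.01)
  expect_equal(h$mobility, 2 * sin(pi * 5 / 200), tolerance = 0.02)

  # integration lowers mobility (a random walk is low-frequency dominated)
  # but raises complexity: the walk's derivative is spectrally much richer
  # than the walk itself, while white noise and its derivative are close
  set.seed(4)
  for (i in 1:5) {
    z <- rnorm(200)
    expect_lt(hjorth(cumsum(z))$mobility, hjorth(z)$mobility)
    expect_gt(hjorth(cumsum(z))$complexity, hjorth(z)$complexity)
  }

  expect_error(hjorth(rep(0, 10)), "degenerate")
  h_const <- hjorth(rep(2, 10))
  expect_equal(h_const$mobility, 0)
  expect_equal(h_const$complexity, 0)
})

test_that("every statistic matches its literal-loop oracle on random windows", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(3:120, 1)
    s <- rnorm(n) * 10^runif(1, -3, 1)
    expect_equal(mav(s), oracle_mav(s), tolerance = 1e-9)
    expect_equal(rms(s), oracle_rms(s), tolerance = 1e-9)
    expect_equal(ssc(s), oracle_ssc(s), tolerance = 1e-9)
    expect_equal(wl(s), oracle_wl(s), tolerance = 1e-9)
    h <- hjorth(s)
    o <- oracle_hjorth(s)
    expect_equal(h$activity, o$activity, tolerance = 1e-9)
    expect_equal(h$mobility, o$mobility, tolerance = 1e-9)
    expect_equal(h$complexity, o$complexity, tolerance = 1e-9)
  }
})

test_that("scaling the window scales each statistic with its degree", {
  set.seed(7)
  s <- rnorm(80)
  for (alpha in c(0.25, 3, 17)) {
    expect_equal(mav(alpha * s), alpha * mav(s))
    expect_equal(rms(alpha * s), alpha * rms(s))
    expect_equal(wl(alpha * s), alpha * wl(s))
    expect_equal(ssc(alpha * s), alpha^2 * ssc(s))
    h1 <- hjorth(s)
    h2 <- hjorth(alpha * s)
    expect_equal(h2$activity, alpha^2 * h1$activity)
    expect_equal(h2$mobility, h1$mobility)
    expect_equal(h2$complexity, h1$complexity)
  }
})

test_that("RMS dominates MAV with equality only for constant magnitude", {
  set.seed(11)
  for (i in 1:50) {
    s <- rnorm(40)
    expect_gte(rms(s), mav(s))
  }
  expect_equal(rms(c(2, -2, 2)), mav(c(2, -2, 2)))
})

test_that("the stacked window observation has the documented layout", {
  set.seed(2)
  w <- matrix(abs(rnorm(80 * 8, 0.1, 0.05)), 80, 8)
  fw <- window_features(w, window_start = 5L, label = 3L)
  expect_equal(dim(fw$D), c(87, 8))
  expect_length(fw$flat, 696)
  # flat is the channel-major flattening of D
  expect_equal(fw$flat, as.vector(fw$D))
  expect_equal(fw$flat[1:87], unname(fw$D[, 1]))
  # feature rows sit below the raw samples in the canonical order
  expect_equal(unname(fw$D[81, 3]), mav(w[, 3]))
  expect_equal(unname(fw$D[82, 3]), rms(w[, 3]))
  expect_equal(unname(fw$D[84, 3]), wl(w[, 3]))
  # permuting channels permutes columns identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  fw_p <- window_features(w[, perm])
  expect_equal(fw_p$D, fw$D[, perm], ignore_attr = TRUE)
  # degenerate all-zero window errors via the hjorth contract
  expect_error(window_features(matrix(0, 10, 2)), "degenerate")
})

test_that("sliding-window enumeration matches the closed-form count", {
  env <- matrix(rnorm(100 * 2), 100, 2)
  sw <- sliding_windows(env, window_spec(80, 1))
  expect_equal(nrow(sw), 21)
  expect_equal(sw$window_start[1], 0L)
  expect_equal(dim(sw$window[[1]]), c(80, 2))
  expect_equal(nrow(sliding_windows(env[1:80, ], window_spec(80, 1))), 1)
  expect_equal(nrow(sliding_windows(env[1:79, ], window_spec(80, 1))), 0)
  # property sweep over (length, l, stride)
  set.seed(3)
  for (i in 1:30) {
    n <- sample(3:60, 1)
    l <- sample(3:15, 1)
    st <- sample(1:7, 1)
    got <- nrow(sliding_windows(matrix(rnorm(n), ncol = 1), window_spec(l, st)))
    expect_equal(got, if (n < l) 0 else floor((n - l) / st) + 1)
  }
})

test_that("bulk feature extraction agrees with per-window computation", {
  set.seed(5)
  env <- matrix(abs(rnorm(140 * 8, 0.1, 0.08)), 140, 8)
  for (spec in list(window_spec(80, 1), window_spec(20, 3))) {
    fm <- extract_features(env, spec)
    expect_equal(nrow(fm$X), floor((140 - spec$length_samples) / spec$stride_samples) + 1)
    for (i in c(1, nrow(fm$X) %/% 2, nrow(fm$X))) {
      st <- fm$window_start[i]
      fw <- window_features(env[(st + 1):(st + spec$length_samples), ])
      expect_equal(fm$X[i, ], fw$flat, tolerance = 1e-8)
    }
  }
  # too-short envelope yields an empty matrix, not an error
  fm0 <- extract_features(matrix(0.1, 10, 8), window_spec(80, 1))
  expect_equal(nrow(fm0$X), 0)
})

test_that("training-set labeling follows the activity interval", {
  cfg <- tiny_config()
  rec <- generate_repetition(cfg, 1, 2)
  sig <- preprocess_recording(rec, trim = FALSE)
  # override detection with a known interval for exact counting
  sig$activity_start <- 100L
  sig$activity_end <- 220L
  sig$has_activity <- TRUE
  wspec <- window_spec(80, 1)
  ts <- build_training_set(list(sig), wspec, include_rest = FALSE)
  expect_equal(nrow(ts$X), 41) # floor((120 - 80)/1) + 1
  expect_true(all(ts$y == 1))
  expect_true(all(ts$window_start >= 100 & ts$window_start + 80 <= 220))
  expect_equal(ncol(ts$X), 8 * 87)

  # with rest windows: fully-outside windows get label 0, straddlers dropped
  ts_r <- build_training_set(list(sig), wspec, include_rest = TRUE)
  expect_setequal(unique(ts_r$y), c(0L, 1L))
  rest_starts <- ts_r$window_start[ts_r$y == 0]
  expect_true(all(rest_starts + 80 <= 100 | rest_starts >= 220))

  # a pure-rest recording contributes only rest labels
  rest <- generate_repetition(cfg, 0, 2)
  sig0 <- preprocess_recording(rest, trim = FALSE)
  ts0 <- build_training_set(list(sig0), wspec, include_rest = TRUE)
  expect_true(all(ts0$y == 0))
})

test_that("feature matrices persist with a self-describing sidecar", {
  env <- matrix(abs(rnorm(60, 0.1, 0.05)), 30, 2)
  fm <- extract_features(env, window_spec(10, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$length_samples, 10)
  expect_equal(meta$stride_samples, 2)
  expect_equal(meta$flattening, "channel-major")
  back <- as.matrix(utils::read.table(path, sep = "\t"))
  expect_equal(unname(back[, -1]), unname(fm$X), tolerance = 1e-12)
})
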