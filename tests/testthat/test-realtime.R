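test_that("vote state starts empty and counts to threshold", {
  st <- vote_state(6, 40)
  expect_equal(st$counts, integer(6))
  expect_false(st$decided)
  expect_equal(vote_state(2, 1)$counts, integer(2))

  # forty consecutive votes for class 2 decide at the fortieth update
  st <- vote_state(6, 40)
  for (i in 0:39) st <- vote_update(st, 2, i)
  expect_true(st$decided)
  expect_equal(st$decided_label, 2L)
  expect_equal(st$decision_window_index, 39L)
  expect_equal(sum(st$counts), 40)

  # interleaved stream: first class to reach tau wins
  st <- vote_state(3, 3)
  for (i in seq_along(c(1, 2, 1, 2, 1))) {
    st <- vote_update(st, c(1, 2, 1, 2, 1)[i], i - 1)
  }
  expect_equal(st$decided_label, 1L)
  expect_equal(st$decision_window_index, 4L)

  # tau = 1 decides immediately
  st <- vote_update(vote_state(6, 1), 5, 0)
  expect_equal(st$decided_label, 5L)

  expect_error(vote_update(st, 1), "already decided")
  expect_error(vote_update(vote_state(3, 2), 7), "0..2")
})

test_that("finalize falls back to No-Gesture when no class reaches tau", {
  st <- vote_state(6, 40)
  for (i in 0:38) st <- vote_update(st, 3, i)
  expect_equal(max(st$counts), 39)
  expect_equal(vote_finalize(st), 0L)
  st40 <- vote_update(st, 3, 39)
  expect_equal(vote_finalize(st40), 3L)
  expect_equal(vote_finalize(vote_state(6, 40)), 0L)
})

test_that("rest votes are counted but only decide when rest_decides is set", {
  st <- vote_state(3, 2)
  st <- vote_update(st, 0, 0)
  st <- vote_update(st, 0, 1)
  expect_false(st$decided)
  expect_equal(st$counts[1], 2L)
  st <- vote_update(st, 1, 2)
  st <- vote_update(st, 1, 3)
  expect_equal(st$decided_label, 1L)

  st2 <- vote_state(3, 2, rest_decides = TRUE)
  st2 <- vote_update(st2, 0, 0)
  st2 <- vote_update(st2, 0, 1)
  expect_true(st2$decided)
  expect_equal(st2$decided_label, 0L)
})

test_that("the strict variant requires exceeding the threshold", {
  st <- vote_state(3, 2, strict = TRUE)
  st <- vote_update(st, 1, 0)
  st <- vote_update(st, 1, 1)
  expect_false(st$decided)
  st <- vote_update(st, 1, 2)
  expect_true(st$decided)
})

test_that("the vote rule matches a brute-force oracle on all short streams", {
  n_classes <- 3
  for (tau in 1:3) {
    for (len in 0:5) {
      streams <- if (len == 0) list(integer(0)) else {
        g <- do.call(expand.grid, rep(list(0:(n_classes - 1)), len))
        lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
      }
      for (labels in streams) {
        o <- oracle_vote(labels, tau, n_classes)
        d <- emgesture:::decide_stream(labels, tau, n_classes)
        expect_identical(d$label, o$label)
        expect_identical(d$decision_index, o$decision_index)
      }
    }
  }
})

test_that("decision latency is nondecreasing in tau for a fixed stream", {
  set.seed(17)
  for (i in 1:20) {
    labels <- sample(0:2, 30, replace = TRUE)
    idx <- sapply(1:6, function(tau) {
      d <- emgesture:::decide_stream(labels, tau, 3)
      if (is.na(d$decision_index)) Inf else d$decision_index
    })
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("streaming recognition decides correctly on clean synthetic input", {
  fix <- tiny_model_fixture()
  rec <- fix$dataset$test$recording[[1]]
  dec <- stream_recognize(fix$model, rec, wspec = fix$wspec, tau = 10)
  expect_equal(dec$label, rec$gesture_label)
  expect_lt(dec$response_ms, (rec$true_offset - rec$true_onset) * 1000 / rec$fs)
  expect_gte(dec$response_ms, 0)
  # decision timestamp is the right edge of the deciding window, and the
  # decision agrees with the brute-force vote oracle replayed on the labels
  o <- oracle_vote(dec$window_labels, 10, fix$model$output_dim)
  expect_equal(dec$label, o$label)
  expect_equal(dec$decision_sample,
               dec$window_start[o$decision_index + 1] + fix$wspec$length_samples)
})

test_that("rest input, short input and unreachable thresholds yield No-Gesture", {
  fix <- tiny_model_fixture()
  rest <- generate_repetition(fix$config, 0, 3, seed = 303)
  dec <- stream_recognize(fix$model, rest, wspec = fix$wspec, tau = 10)
  expect_equal(dec$label, 0L)

  short <- generate_repetition(fix$config, 0, 0.05, seed = 304)
  dec_short <- stream_recognize(fix$model, short, wspec = fix$wspec, tau = 10)
  expect_equal(dec_short$label, 0L)
  expect_true(is.na(dec_short$response_ms))

  rec <- fix$dataset$test$recording[[2]]
  dec_big <- stream_recognize(fix$model, rec, wspec = fix$wspec,
                              tau = nrow(rec$samples) + 1)
  expect_equal(dec_big$label, 0L)
})

test_that("streaming window labels equal batch labels on the same samples", {
  fix <- tiny_model_fixture()
  rec <- fix$dataset$test$recording[[3]]
  dec <- stream_recognize(fix$model, rec, wspec = fix$wspec,
                          tau = .Machine$integer.max)
  sig <- preprocess_recording(rec, trim = FALSE)
  batch <- predict(fix$model, extract_features(sig$envelope, fix$wspec))
  expect_identical(dec$window_labels, batch)
})

test_that("no overshoot: the deciding class holds exactly tau votes", {
  fix <- tiny_model_fixture()
  for (tau in c(5, 15)) {
    rec <- fix$dataset$test$recording[[4]]
    dec <- stream_recognize(fix$model, rec, wspec = fix$wspec, tau = tau)
    if (dec$label > 0) {
      consumed <- dec$window_labels[seq_len(match(dec$decision_sample - fix$wspec$length_samples,
                                                  dec$window_start))]
      expect_equal(sum(consumed == dec$label), tau)
    }
  }
})

test_that("latency respects the tau-votes lower bound", {
  fix <- tiny_model_fixture()
  wspec <- fix$wspec
  tau <- 12
  for (rec in fix$dataset$test$recording[1:4]) {
    dec <- stream_recognize(fix$model, rec, wspec = wspec, tau = tau)
    if (dec$label == rec$gesture_label && dec$label > 0) {
      first_in <- dec$window_start[which(dec$window_labels == dec$label)[1]]
      lower <- (tau - 1) * wspec$stride_samples * 1000 / rec$fs
      expect_gte((dec$decision_sample - wspec$length_samples - first_in) *
                   1000 / rec$fs, lower)
    }
  }
})

test_that("session recognition returns one tidy row per repetition", {
  fix <- tiny_model_fixture()
  decs <- recognize_session(fix$model, fix$dataset$test[1:4, ],
                            wspec = fix$wspec, tau = 10)
  expect_equal(nrow(decs), 4)
  expect_true(all(c("gesture", "predicted", "response_ms") %in% names(decs)))
})
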