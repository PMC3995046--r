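# epochs holding one arbitrary waveform on one channel
wave_epochs <- function(waves, srate = 1000, tmin = -100) {
  if (is.null(dim(waves))) waves <- matrix(waves, nrow = 1)
  n_ep <- nrow(waves); n_s <- ncol(waves)
  data <- array(0, dim = c(n_ep, 1, n_s))
  for (e in seq_len(n_ep)) data[e, 1, ] <- waves[e, ]
  ev <- eventlist(tibble::tibble(code = rep(1L, n_ep), onset = seq_len(n_ep)),
                  srate = srate)
  epoched_eeg(data, srate = srate, tmin = tmin,
              tmax = tmin + n_s * 1000 / srate, chan_labels = "ch1",
              epochs = tibble::tibble(epoch = seq_len(n_ep),
                                      item = seq_len(n_ep),
                                      bins = rep(list(1L), n_ep)),
              events = ev)
}

test_that("each detector flags its target morphology and spares clean data", {
  n <- 600
  step_wave <- c(rep(-50, n / 2), rep(50, n / 2))
  ep <- wave_epochs(step_wave)
  out <- detect_artifacts(ep, detector_spec("step_like", channels = 1,
                                            threshold = 60, width_ms = 400,
                                            step_ms = 10, flag = 3))
  expect_true(out$flags[1, 1])
  expect_true(out$flags[1, 3])
  expect_true(out$chan_marks[1, 1])
  # flags mirrored onto the home event
  expect_equal(out$events$events$artifact_flags[1], "10100000")

  flat_wave <- c(rnorm(150, sd = 10), rep(3.2, 300), rnorm(150, sd = 10))
  outf <- detect_artifacts(wave_epochs(flat_wave),
                           detector_spec("flatline", channels = 1, threshold = 1,
                                         min_duration_ms = 200, flag = 4))
  expect_true(outf$flags[1, 4])

  sine <- 10 * sin(2 * pi * 10 * seq(0, 0.599, by = 1e-3))
  outs <- detect_artifacts(wave_epochs(sine),
                           detector_spec("moving_p2p", channels = 1, threshold = 50,
                                         width_ms = 200, step_ms = 20))
  expect_false(any(outs$flags))

  spike <- rep(0, n); spike[300] <- 40
  outd <- detect_artifacts(wave_epochs(spike),
                           detector_spec("sample_diff", channels = 1, threshold = 30))
  expect_true(outd$flags[1, 1])

  outt <- detect_artifacts(wave_epochs(rep(0, n)),
                           detector_spec("simple_threshold", channels = 1,
                                         threshold = c(-100, 100)))
  expect_false(any(outt$flags))
})

test_that("detectors except simple_threshold are translation invariant", {
  set.seed(3)
  wave <- rnorm(600, sd = 20)
  for (alg in c("moving_p2p", "step_like", "flatline", "sample_diff")) {
    spec <- detector_spec(alg, channels = 1, threshold = 40, width_ms = 200,
                          step_ms = 20, min_duration_ms = 100)
    a <- detect_artifacts(wave_epochs(wave), spec)$flags[1, 1]
    b <- detect_artifacts(wave_epochs(wave + 500), spec)$flags[1, 1]
    expect_identical(a, b)
  }
  spec <- detector_spec("simple_threshold", channels = 1, threshold = 100)
  expect_false(detect_artifacts(wave_epochs(wave * 0), spec)$flags[1, 1])
  expect_true(detect_artifacts(wave_epochs(wave * 0 + 500), spec)$flags[1, 1])
})

test_that("the step detector equals the scaled cross-covariance with a step template", {
  set.seed(4)
  srate <- 1000
  for (rep in 1:20) {
    x <- rnorm(400, sd = 15)
    w <- 100   # samples per half window
    spec <- detector_spec("step_like", channels = 1, threshold = 1e9,
                          width_ms = 200, step_ms = 10)
    got <- erpkit:::detector_statistic(x, spec, srate)
    # brute force: cross-covariance with a +/-1 step at every position / half-width
    starts <- seq(0L, length(x) - 2L * w, by = 10L)
    if (starts[length(starts)] != length(x) - 2L * w)
      starts <- c(starts, length(x) - 2L * w)
    tmpl <- c(rep(-1, w), rep(1, w))
    want <- max(vapply(starts, function(s0)
      abs(sum(x[(s0 + 1):(s0 + 2 * w)] * tmpl)) / w, 0))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("raising a detector threshold never increases the flag count", {
  set.seed(6)
  waves <- matrix(rnorm(30 * 600, sd = 30), nrow = 30)
  ep <- wave_epochs(waves)
  counts <- vapply(c(20, 50, 80, 120, 200), function(th) {
    out <- detect_artifacts(ep, detector_spec("moving_p2p", channels = 1,
                                              threshold = th, width_ms = 200,
                                              step_ms = 20))
    sum(out$flags[, 1])
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("clear_flags removes exactly the requested flags, on epochs and events", {
  ep <- wave_epochs(c(rep(-50, 300), rep(50, 300)))
  ep <- detect_artifacts(ep, detector_spec("step_like", channels = 1,
                                           threshold = 60, width_ms = 400,
                                           step_ms = 10, flag = 3))
  part <- clear_flags(ep, 1L)
  expect_false(part$flags[1, 1])
  expect_true(part$flags[1, 3])
  expect_equal(part$events$events$artifact_flags[1], "00100000")
  all_clear <- clear_flags(ep, 1:8)
  expect_false(any(all_clear$flags))
  expect_false(any(all_clear$chan_marks))
  expect_equal(all_clear$events$events$artifact_flags[1], "00000000")
  # clearing clean data is a no-op
  clean <- wave_epochs(rep(0, 600))
  expect_false(any(clear_flags(clean, 1:8)$flags))
})

test_that("continuous rejection deletes merged spans, splices boundaries, drops events", {
  srate <- 1000
  n <- 10 * srate
  x <- rnorm(n, sd = 5)
  x[4000:5000] <- x[4000:5000] + 500 * sin(seq(0, pi, length.out = 1001))
  ev <- eventlist(tibble::tibble(code = c(1L, 2L, 3L),
                                 onset = c(2, 4.5, 8)), srate = srate)
  eeg <- continuous_eeg(matrix(x, 1), srate = srate, events = ev)
  out <- reject_continuous(eeg, channels = 1, threshold = 300, width_ms = 500,
                           pad_ms = 100)
  expect_equal(out$n_deleted_segments, 1L)
  expect_length(out$boundaries, 1L)
  # the event inside the deleted span is gone; others survive
  expect_equal(out$events$events$code, c(1L, 3L))
  expect_lt(ncol(out$data), n)
  expect_true(max(out$data[1, ]) - min(out$data[1, ]) < 300)

  clean <- continuous_eeg(matrix(rnorm(n, sd = 5), 1), srate = srate)
  outc <- reject_continuous(clean, 1, threshold = 300, width_ms = 500)
  expect_equal(ncol(outc$data), n)
  expect_length(outc$boundaries, 0L)
})

test_that("epochs never span a splice left by continuous rejection", {
  srate <- 500
  n <- 30 * srate
  set.seed(8)
  x <- rnorm(n, sd = 5)
  x[7000:7100] <- 800
  onsets <- seq(1, 28, by = 0.9)
  ev <- eventlist(tibble::tibble(code = rep(1L, length(onsets)), onset = onsets,
                                 bins = rep(list(1L), length(onsets))),
                  srate = srate)
  eeg <- continuous_eeg(matrix(x, 1), srate = srate, events = ev)
  out <- reject_continuous(eeg, 1, threshold = 300, width_ms = 400, pad_ms = 200)
  expect_gt(length(out$boundaries), 0L)
  suppressMessages(ep <- extract_epochs(out, -200, 800))
  # verify directly: no epoch window contains a boundary strictly inside
  for (i in seq_len(nrow(ep$epochs))) {
    e <- ep$events$events
    smp <- round(e$onset[match(ep$epochs$item[i], e$item)] * srate)
    s0 <- smp + round(-200 * srate / 1000)
    s1 <- s0 + dim(ep$data)[3]
    expect_false(any(out$boundaries > s0 & out$boundaries < s1))
  }
})

test_that("rejection reports proportions and the 25% exclusion policy", {
  waves <- matrix(0, 100, 300)
  ep <- wave_epochs(waves, srate = 1000)
  ep$flags[1:30, 1] <- TRUE
  r <- rejection_report(ep)
  expect_equal(r$n_total, 100L)
  expect_equal(r$n_flagged, 30L)
  expect_equal(r$proportion, 0.3)
  expect_true(r$exclude_subject)              # 30% > default 25%
  expect_false(rejection_report(ep, 0.5)$exclude_subject)

  ep0 <- wave_epochs(waves)
  r0 <- rejection_report(ep0)
  expect_equal(r0$proportion, 0)
  expect_false(r0$exclude_subject)
  expect_equal(r0$by_bin$n_total, 100L)
})

test_that("feature events are inserted once per excursion, in onset order", {
  srate <- 500
  n <- 20 * srate
  x <- rnorm(n, sd = 3)
  blink <- function(at) {
    idx <- round(at * srate) + seq_len(round(0.2 * srate))
    x[idx] <<- x[idx] + 200 * 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
  }
  blink(5); blink(10)
  eeg <- continuous_eeg(matrix(x, 1), srate = srate, chan_labels = "VEOG")
  spec <- detector_spec("moving_p2p", channels = 1, threshold = 100,
                        width_ms = 400, step_ms = 20)
  out <- insert_feature_events(eeg, 1, spec, new_code = 901L, label = "blink")
  ins <- out$events$events[out$events$events$code == 901L, ]
  expect_equal(nrow(ins), 2L)
  expect_false(is.unsorted(ins$onset))
  expect_true(abs(ins$onset[1] - 5) < 0.5)
  expect_true(abs(ins$onset[2] - 10) < 0.5)

  flat <- continuous_eeg(matrix(0, 1, n), srate = srate)
  outf <- insert_feature_events(flat, 1, spec, new_code = 901L)
  expect_equal(nrow(outf$events$events), 0L)

  # colliding code warns but inserts
  ev <- eventlist(tibble::tibble(code = 901L, onset = 1), srate = srate)
  eeg2 <- continuous_eeg(matrix(x, 1), srate = srate, events = ev)
  expect_warning(insert_feature_events(eeg2, 1, spec, new_code = 901L),
                 "collides")
})
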