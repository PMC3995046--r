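make_binned_eeg <- function(onsets, codes = NULL, bins = NULL, srate = 1000,
                            n_s = NULL, n_ch = 1, boundaries = integer()) {
  if (is.null(codes)) codes <- rep(1L, length(onsets))
  if (is.null(bins)) bins <- rep(list(1L), length(onsets))
  if (is.null(n_s)) n_s <- round(max(onsets) * srate) + srate
  ev <- eventlist(tibble::tibble(code = codes, onset = onsets, bins = bins),
                  srate = srate)
  continuous_eeg(matrix(0, n_ch, n_s), srate = srate, events = ev,
                 boundaries = boundaries)
}

test_that("epoch windows are half-open with time zero at the right offset", {
  eeg <- make_binned_eeg(c(1, 2, 3))
  ep <- extract_epochs(eeg, -100, 500)
  expect_equal(dim(ep$data), c(3, 1, 600))
  tm <- time_axis(ep)
  expect_equal(tm[1], -100)
  expect_equal(tm[101], 0)          # time zero at offset 100
  expect_equal(tm[600], 499)        # tmax excluded
  expect_error(extract_epochs(eeg, 100, 100), "tmax must exceed tmin")
})

test_that("epochs that do not fit or cross a boundary are skipped and counted", {
  eeg <- make_binned_eeg(c(0.05, 2, 3))     # first event 50 ms from start
  expect_message(ep <- extract_epochs(eeg, -100, 500), "1 event\\(s\\) skipped")
  expect_equal(ep$n_skipped, 1L)
  expect_equal(dim(ep$data)[1], 2L)

  # boundary at sample 2500 cuts through the epoch of the event at 2.3 s
  eeg2 <- make_binned_eeg(c(1, 2.3, 4), boundaries = 2500L)
  expect_message(ep2 <- extract_epochs(eeg2, -200, 500), "skipped")
  expect_equal(dim(ep2$data)[1], 2L)

  # events with no bins are not epoched
  eeg3 <- make_binned_eeg(c(1, 2), bins = list(1L, integer()))
  ep3 <- extract_epochs(eeg3, -100, 500)
  expect_equal(dim(ep3$data)[1], 1L)

  eeg4 <- make_binned_eeg(c(1, 2), bins = list(integer(), integer()))
  expect_error(extract_epochs(eeg4, -100, 500), "nothing to epoch")
})

test_that("baseline correction zeroes the baseline mean", {
  ep <- make_constant_epochs(7)
  out <- baseline_correct(ep, -100, 0)
  expect_true(all(out$data == 0))

  set.seed(2)
  ep2 <- make_constant_epochs(rnorm(4))
  ep2$data <- ep2$data + array(rnorm(length(ep2$data)), dim = dim(ep2$data))
  out2 <- baseline_correct(ep2, -100, 0)
  idx <- which(time_axis(out2) < 0)
  for (e in 1:4)
    expect_lt(abs(mean(out2$data[e, 1, idx])), 1e-9)
  expect_error(baseline_correct(ep2, -100, 600), "outside epoch")
})

test_that("epoch selection partitions odd/even, draws reproducibly, and validates n", {
  ep <- make_constant_epochs(1:5)
  odd <- select_epochs(ep, 1, "odd")
  even <- select_epochs(ep, 1, "even")
  expect_equal(odd$data[, 1, 1], c(1, 3, 5))
  expect_equal(even$data[, 1, 1], c(2, 4))
  expect_equal(sort(c(odd$data[, 1, 1], even$data[, 1, 1])), 1:5)

  r1 <- select_epochs(ep, 1, "random_n", n = 3, seed = 7)
  r2 <- select_epochs(ep, 1, "random_n", n = 3, seed = 7)
  expect_identical(r1$data, r2$data)

  expect_error(select_epochs(ep, 1, "first_n", n = 9), "requested 9 of 5")
  expect_error(select_epochs(ep, 1, "random_n", n = 3), "seed is required")
})

test_that("artifact modes average the right epochs with the right counts", {
  ep <- make_constant_epochs(c(1, 2, 3, 4))
  ep$flags[3, 1] <- TRUE
  excl <- average_epochs(ep, "exclude_marked")
  expect_equal(excl$data[1, 1, 1], 7 / 3)
  expect_equal(excl$counts$n_accepted, 3L)
  expect_equal(excl$counts$n_rejected, 1L)

  incl <- average_epochs(ep, "include_all")
  expect_equal(incl$data[1, 1, 1], 2.5)

  only <- average_epochs(ep, "only_marked")
  expect_equal(only$data[1, 1, 1], 3)
  expect_equal(only$counts$n_accepted, 1L)

  # include_all equals the count-weighted mean of exclude and only
  w <- excl$counts$n_accepted + only$counts$n_accepted
  expect_equal(incl$data[1, 1, ],
               (excl$counts$n_accepted * excl$data[1, 1, ] +
                only$counts$n_accepted * only$data[1, 1, ]) / w)
})

test_that("averaging identical epochs returns the epoch; empty bins warn with zeros", {
  ep <- make_constant_epochs(c(5, 5, 5))
  ep$data <- ep$data + rep(sin(seq_len(dim(ep$data)[3]) / 10), each = 3)
  erp <- average_epochs(ep, "include_all")
  expect_equal(erp$data[1, 1, ], ep$data[1, 1, ])

  ep2 <- make_constant_epochs(c(1, 2), bins = list(1L, 2L))
  ep2$flags[2, 1] <- TRUE
  expect_warning(erp2 <- average_epochs(ep2, "exclude_marked"),
                 "bin 2.*zero waveform")
  expect_equal(erp2$data[2, 1, 1], 0)
  expect_equal(erp2$counts$n_accepted, c(1L, 0L))

  ep3 <- make_constant_epochs(1)
  ep3$flags[1, 1] <- TRUE
  expect_error(average_epochs(ep3, "exclude_marked"), "no qualifying epochs")
})

test_that("multi-file averaging equals averaging the concatenation", {
  a <- make_constant_epochs(c(1, 2))
  b <- make_constant_epochs(c(3, 4, 5))
  m <- average_multi(list(a, b), "include_all")
  one <- average_epochs(make_constant_epochs(1:5), "include_all")
  expect_equal(m$data, one$data)
  expect_equal(m$counts$n_accepted, 5L)

  bad <- make_constant_epochs(c(1, 2), srate = 500)
  expect_error(average_multi(list(a, bad)), "file 2.*sampling rate")
  expect_error(average_multi(list()), "empty file list")
})

test_that("grand averages weight subjects as requested and check axes", {
  e1 <- make_constant_erp(1, n_accepted = 10)
  e2 <- make_constant_erp(2, n_accepted = 30)
  e3 <- make_constant_erp(3, n_accepted = 20)
  g <- grand_average(list(e1, e2, e3))
  expect_equal(g$data[1, 1, 1], 2)
  gw <- grand_average(list(e1, e2), weighted = TRUE)
  expect_equal(gw$data[1, 1, 1], 1.75)         # (10*1 + 30*2) / 40
  # permutation invariance in subject order
  g2 <- grand_average(list(e3, e1, e2))
  expect_equal(g2$data, g$data)

  expect_error(grand_average(list(e1)), "at least 2")
  e4 <- make_constant_erp(1, srate = 500)
  expect_error(grand_average(list(e1, e4)), "axis mismatch")
})

test_that("leave-one-out grand averages satisfy the jackknife identity", {
  erps <- lapply(c(1, 2, 3), make_constant_erp)
  loo <- jackknife_set(erps)
  expect_equal(vapply(loo, function(e) e$data[1, 1, 1], 0), c(2.5, 2, 1.5))
  mean_loo <- Reduce(`+`, lapply(loo, function(e) e$data)) / 3
  full <- grand_average(erps)$data
  expect_equal(mean_loo, full, tolerance = 1e-9)

  two <- jackknife_set(list(make_constant_erp(0), make_constant_erp(10)))
  expect_equal(vapply(two, function(e) e$data[1, 1, 1], 0), c(10, 0))

  expect_equal(jackknife_adjust(10, 11), 1)
  expect_equal(jackknife_adjust(0, 5), 0)
  expect_equal(jackknife_adjust(-4, 3), -2)
  expect_error(jackknife_adjust(1, 1), "at least 2")
})

test_that("bin-label permutation conserves counts, is seeded, and rejects multi-bin epochs", {
  ep <- make_constant_epochs(1:4, bins = list(1L, 1L, 2L, 2L))
  p1 <- permute_bin_labels(ep, seed = 3)
  expect_equal(sort(unlist(p1$epochs$bins)), c(1L, 1L, 2L, 2L))
  expect_identical(p1$data, ep$data)
  p2 <- permute_bin_labels(ep, seed = 3)
  expect_identical(unlist(p1$epochs$bins), unlist(p2$epochs$bins))

  epm <- make_constant_epochs(1:2, bins = list(c(1L, 2L), 1L))
  expect_error(permute_bin_labels(epm, seed = 1), "exactly one bin")
})

test_that("the permutation null distribution of a bin difference is centered at zero", {
  set.seed(11)
  n <- 40
  vals <- rnorm(n)
  ep <- make_constant_epochs(vals, bins = as.list(rep(c(1L, 2L), n / 2)))
  diffs <- vapply(1:500, function(s) {
    p <- permute_bin_labels(ep, seed = s)
    b <- unlist(p$epochs$bins)
    mean(vals[b == 2L]) - mean(vals[b == 1L])
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})
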