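#' Extract bin-assigned epochs from continuous EEG
#'
#' Cuts one fixed-length segment around every enabled event that has at least
#' one bin assignment. The window is half-open `[tmin, tmax)` ms relative to
#' the event; in samples it runs from `e + round(tmin*srate/1000)` for
#' `round((tmax - tmin)*srate/1000)` samples, where `e` is the event's sample.
#' Events whose window does not fit inside the recording, or whose window
#' would cross a boundary marker (a discontinuity must never be averaged as
#' continuous data), are skipped; the number of skips is reported and stored
#' in the result as `n_skipped`.
#'
#' @param eeg An `erp_continuous` whose events have been through
#'   [assign_bins()].
#' @param tmin,tmax Epoch window in ms; `tmin <= 0 < tmax`.
#' @return An `erp_epochs`.
#' @export
extract_epochs <- function(eeg, tmin, tmax) {
  stopifnot(inherits(eeg, "erp_continuous"))
  if (tmax <= tmin) stop("tmax must exceed tmin", call. = FALSE)
  e <- eeg$events$events
  cand <- which(e$enabled & lengths(e$bins) > 0L)
  if (!length(cand)) stop("nothing to epoch: no enabled events with bins", call. = FALSE)
  fs <- eeg$srate
  n_samp <- round((tmax - tmin) * fs / 1000)
  off <- round(tmin * fs / 1000)
  ns_rec <- ncol(eeg$data)
  keep <- logical(length(cand))
  starts <- integer(length(cand))
  for (i in seq_along(cand)) {
    ev_smp <- round(e$onset[cand[i]] * fs)           # 0-based
    s0 <- ev_smp + off
    s1 <- s0 + n_samp                                 # exclusive
    ok <- s0 >= 0 && s1 <= ns_rec &&
      !any(eeg$boundaries > s0 & eeg$boundaries < s1)
    keep[i] <- ok
    starts[i] <- s0
  }
  n_skipped <- sum(!keep)
  cand <- cand[keep]; starts <- starts[keep]
  if (!length(cand)) stop("nothing to epoch: all candidate epochs skipped", call. = FALSE)
  data <- array(0, dim = c(length(cand), nrow(eeg$data), n_samp))
  for (i in seq_along(cand))
    data[i, , ] <- eeg$data[, (starts[i] + 1L):(starts[i] + n_samp), drop = FALSE]
  ep <- epoched_eeg(
    data, srate = fs, tmin = tmin, tmax = tmax, chan_labels = eeg$chan_labels,
    epochs = tibble::tibble(epoch = seq_along(cand), item = e$item[cand],
                            bins = e$bins[cand]),
    events = eeg$events
  )
  ep$n_skipped <- n_skipped
  if (n_skipped > 0)
    message(n_skipped, " event(s) skipped (window outside recording or crossing a boundary)")
  ep$history <- eeg$history
  append_history(ep, sprintf("extract_epochs(x, tmin = %.6g, tmax = %.6g)", tmin, tmax))
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline window
#' `[base_start, base_end)` ms. The conventional choice is the pre-stimulus
#' interval `[tmin, 0)`, which is the default.
#'
#' @param ep An `erp_epochs`.
#' @param base_start,base_end Baseline window in ms; must lie within the epoch.
#' @return The corrected `erp_epochs`.
#' @export
baseline_correct <- function(ep, base_start = ep$tmin, base_end = 0) {
  stopifnot(inherits(ep, "erp_epochs"))
  idx <- window_sample_idx(ep, base_start, base_end)
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(base)   # recycles over the sample axis
  ep <- assert_finite(ep)
  append_history(ep, sprintf("baseline_correct(x, base_start = %.6g, base_end = %.6g)",
                             base_start, base_end))
}

# samples (1-based) whose times lie in [start, end) ms
window_sample_idx <- function(x, start, end, what = "window") {
  if (end <= start) stop(what, " end must exceed start", call. = FALSE)
  tm <- time_axis(x)
  if (start < x$tmin - 1e-9 || end > x$tmax + 1e-9)
    stop(sprintf("%s [%g, %g) outside epoch [%g, %g)", what, start, end, x$tmin, x$tmax),
         call. = FALSE)
  idx <- which(tm >= start - 1e-9 & tm < end - 1e-9)
  if (!length(idx)) stop(what, " contains no samples", call. = FALSE)
  idx
}

#' Select a subset of the epochs in a bin
#'
#' Supports split-half reliability (odd vs even numbered occurrences within
#' the bin), trial-count equating (`first_n`, or a seeded `random_n` draw),
#' or simply restricting to one bin (`all`). Occurrence numbering is 1-based
#' in within-bin order.
#'
#' @param ep An `erp_epochs`.
#' @param bin Bin number to select from.
#' @param mode One of `"all"`, `"odd"`, `"even"`, `"first_n"`, `"random_n"`.
#' @param n Number of epochs for `first_n` / `random_n`.
#' @param seed Integer seed, required for `random_n` (draws are reproducible).
#' @return An `erp_epochs` containing only the selected epochs.
#' @export
select_epochs <- function(ep, bin, mode = c("all", "odd", "even", "first_n", "random_n"),
                          n = NULL, seed = NULL) {
  stopifnot(inherits(ep, "erp_epochs"))
  mode <- match.arg(mode)
  in_bin <- which(vapply(ep$epochs$bins, function(b) bin %in% b, TRUE))
  if (!length(in_bin)) stop("no epochs in bin ", bin, call. = FALSE)
  if (mode %in% c("first_n", "random_n")) {
    if (is.null(n)) stop("n is required for mode ", mode, call. = FALSE)
    if (n > length(in_bin))
      stop(sprintf("requested %d of %d epochs in bin %d", n, length(in_bin), bin),
           call. = FALSE)
  }
  sel <- switch(mode,
    all = in_bin,
    odd = in_bin[seq_along(in_bin) %% 2L == 1L],
    even = in_bin[seq_along(in_bin) %% 2L == 0L],
    first_n = in_bin[seq_len(n)],
    random_n = {
      if (is.null(seed)) stop("seed is required for mode random_n", call. = FALSE)
      sort(in_bin[with_seed(seed, sample.int(length(in_bin), n))])
    })
  out <- subset_epochs(ep, sel)
  append_history(out, sprintf(
    "select_epochs(x, bin = %d, mode = \"%s\"%s%s)", bin, mode,
    if (is.null(n)) "" else sprintf(", n = %d", n),
    if (is.null(seed)) "" else sprintf(", seed = %d", seed)))
}

subset_epochs <- function(ep, sel) {
  ep$data <- ep$data[sel, , , drop = FALSE]
  ep$epochs <- ep$epochs[sel, ]
  ep$epochs$epoch <- seq_len(nrow(ep$epochs))
  ep$flags <- ep$flags[sel, , drop = FALSE]
  ep$chan_marks <- ep$chan_marks[sel, , drop = FALSE]
  ep
}

# evaluate code with a temporary, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Average epochs into an ERP set
#'
#' For each bin, averages the qualifying epochs sample-wise per channel. An
#' epoch assigned to several bins contributes to all of them. Three artifact
#' modes are available: exclude the epochs marked for rejection (flag 1),
#' ignore the marks and average everything, or average only the marked epochs
#' (useful for inspecting what the rejected artifacts look like). Bins with no
#' qualifying epoch yield a zero waveform with a warning and an accepted count
#' of zero. Per-bin accounting records the epochs averaged, the epochs
#' carrying the master artifact flag, and rejected counts per artifact flag.
#'
#' @param ep An `erp_epochs`.
#' @param artifact_mode `"exclude_marked"`, `"include_all"` or `"only_marked"`.
#' @param subject Subject identifier stored in the result.
#' @return An `erp_set`.
#' @export
average_epochs <- function(ep,
                           artifact_mode = c("exclude_marked", "include_all", "only_marked"),
                           subject = "") {
  stopifnot(inherits(ep, "erp_epochs"))
  artifact_mode <- match.arg(artifact_mode)
  bins <- sort(unique(unlist(ep$epochs$bins)))
  flagged <- ep$flags[, 1]
  qual <- switch(artifact_mode,
    exclude_marked = !flagged,
    include_all = rep(TRUE, length(flagged)),
    only_marked = flagged)
  if (!any(qual)) stop("no qualifying epochs in any bin", call. = FALSE)
  n_chan <- dim(ep$data)[2]; n_samp <- dim(ep$data)[3]
  data <- array(0, dim = c(length(bins), n_chan, n_samp))
  counts <- tibble::tibble(bin = bins, n_accepted = 0L, n_rejected = 0L)
  rbf <- matrix(0L, length(bins), 8L)
  any_used <- FALSE
  for (i in seq_along(bins)) {
    in_bin <- vapply(ep$epochs$bins, function(b) bins[i] %in% b, TRUE)
    use <- which(in_bin & qual)
    counts$n_accepted[i] <- length(use)
    counts$n_rejected[i] <- sum(in_bin & flagged)
    rbf[i, ] <- colSums(ep$flags[in_bin, , drop = FALSE])
    if (length(use)) {
      data[i, , ] <- apply(ep$data[use, , , drop = FALSE], c(2, 3), mean)
      any_used <- TRUE
    } else {
      warning("bin ", bins[i], ": no qualifying epochs; zero waveform", call. = FALSE)
    }
  }
  if (!any_used) stop("no qualifying epochs in any bin", call. = FALSE)
  erp <- erp_set(data, srate = ep$srate, tmin = ep$tmin, tmax = ep$tmax,
                 bin_labels = paste0("bin", bins), chan_labels = ep$chan_labels,
                 counts = counts, rejected_by_flag = rbf, subject = subject)
  erp$bin_numbers <- bins
  erp$history <- ep$history
  append_history(erp, sprintf("average_epochs(x, artifact_mode = \"%s\")", artifact_mode))
}

#' Average epochs pooled across several epoched files
#'
#' Equivalent to concatenating the epochs of all files (trial blocks are often
#' saved as separate recordings) and averaging once. All files must share the
#' sampling rate, epoch window, channels and bin universe.
#'
#' @param files List of `erp_epochs`.
#' @inheritParams average_epochs
#' @return An `erp_set`.
#' @export
average_multi <- function(files, artifact_mode = c("exclude_marked", "include_all", "only_marked"),
                          subject = "") {
  artifact_mode <- match.arg(artifact_mode)
  if (!length(files)) stop("empty file list", call. = FALSE)
  ref <- files[[1]]
  for (i in seq_along(files)) {
    f <- files[[i]]
    if (!inherits(f, "erp_epochs")) stop("file ", i, ": not an erp_epochs", call. = FALSE)
    if (f$srate != ref$srate) stop("file ", i, ": sampling rate mismatch", call. = FALSE)
    if (f$tmin != ref$tmin || f$tmax != ref$tmax)
      stop("file ", i, ": epoch window mismatch", call. = FALSE)
    if (!identical(f$chan_labels, ref$chan_labels))
      stop("file ", i, ": channel mismatch", call. = FALSE)
  }
  n_eps <- vapply(files, function(f) dim(f$data)[1], 0L)
  data <- array(0, dim = c(sum(n_eps), dim(ref$data)[2], dim(ref$data)[3]))
  at <- 0L
  epochs <- list(); flags <- list(); marks <- list()
  for (f in files) {
    ne <- dim(f$data)[1]
    data[(at + 1L):(at + ne), , ] <- f$data
    epochs[[length(epochs) + 1L]] <- f$epochs
    flags[[length(flags) + 1L]] <- f$flags
    marks[[length(marks) + 1L]] <- f$chan_marks
    at <- at + ne
  }
  ep_tbl <- dplyr::bind_rows(epochs)
  ep_tbl$epoch <- seq_len(nrow(ep_tbl))
  merged <- epoched_eeg(data, srate = ref$srate, tmin = ref$tmin, tmax = ref$tmax,
                        chan_labels = ref$chan_labels, epochs = ep_tbl,
                        events = ref$events,
                        flags = do.call(rbind, flags),
                        chan_marks = do.call(rbind, marks))
  average_epochs(merged, artifact_mode, subject = subject)
}

#' Grand-average ERP sets across subjects
#'
#' Per bin, channel and sample, the mean across subjects. By default each
#' subject carries equal weight (conventional ERP practice); with
#' `weighted = TRUE` subjects are weighted by their per-bin accepted trial
#' counts.
#'
#' @param erps List of at least two `erp_set`s with identical axes.
#' @param weighted Weight subjects by per-bin `n_accepted`?
#' @return An `erp_set`; `n_accepted` counts are summed across subjects.
#' @export
grand_average <- function(erps, weighted = FALSE) {
  check_erp_axes(erps, min_n = 2L)
  ref <- erps[[1]]
  nb <- dim(ref$data)[1]
  data <- array(0, dim = dim(ref$data))
  for (b in seq_len(nb)) {
    w <- if (weighted) vapply(erps, function(e) as.numeric(e$counts$n_accepted[b]), 0)
         else rep(1, length(erps))
    if (sum(w) == 0) w <- rep(1, length(erps))
    acc <- 0
    for (i in seq_along(erps)) acc <- acc + w[i] * erps[[i]]$data[b, , ]
    data[b, , ] <- acc / sum(w)
  }
  counts <- ref$counts
  counts$n_accepted <- Reduce(`+`, lapply(erps, function(e) e$counts$n_accepted))
  counts$n_rejected <- Reduce(`+`, lapply(erps, function(e) e$counts$n_rejected))
  out <- erp_set(data, srate = ref$srate, tmin = ref$tmin, tmax = ref$tmax,
                 bin_labels = ref$bin_labels, chan_labels = ref$chan_labels,
                 counts = counts, subject = "grand")
  append_history(out, sprintf("grand_average(x, weighted = %s)", weighted))
}

check_erp_axes <- function(erps, min_n = 1L) {
  if (length(erps) < min_n)
    stop("need at least ", min_n, " ERP sets", call. = FALSE)
  ref <- erps[[1]]
  for (i in seq_along(erps)) {
    e <- erps[[i]]
    if (!inherits(e, "erp_set")) stop("element ", i, ": not an erp_set", call. = FALSE)
    if (!identical(dim(e$data), dim(ref$data)) || e$srate != ref$srate ||
        e$tmin != ref$tmin || !identical(e$chan_labels, ref$chan_labels))
      stop("element ", i, ": axis mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

#' Leave-one-out jackknife grand averages
#'
#' Returns N grand averages, the i-th omitting subject i. Statistics that
#' involve non-linear transforms of noisy single-subject waveforms (onset
#' latencies above all) gain enormously in power when measured from these
#' smooth leave-one-out waveforms; the resulting test statistic must then be
#' rescaled with [jackknife_adjust()]. The mean of the N outputs equals the
#' full grand average.
#'
#' @param erps List of N >= 2 `erp_set`s.
#' @return List of N `erp_set`s.
#' @export
jackknife_set <- function(erps) {
  check_erp_axes(erps, min_n = 2L)
  lapply(seq_along(erps), function(i) {
    rest <- erps[-i]
    g <- if (length(rest) == 1L) rest[[1]] else grand_average(rest, weighted = FALSE)
    g$subject <- paste0("loo_", i)
    g
  })
}

#' Jackknife adjustment of a leave-one-out statistic
#'
#' A t (or sqrt-F, or r-to-t) statistic computed across leave-one-out grand
#' averages overstates its evidence because the N leave-one-out values are
#' nearly identical; dividing by N - 1 restores the correct scale.
#'
#' @param statistic The statistic computed from leave-one-out measurements.
#' @param n_subjects Number of subjects N (>= 2).
#' @return `statistic / (n_subjects - 1)`.
#' @export
jackknife_adjust <- function(statistic, n_subjects) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  statistic / (n_subjects - 1)
}

#' Permute bin labels across epochs
#'
#' Builds a permutation surrogate: bin labels are randomly reassigned across
#' epochs (a seeded uniform permutation), conserving the per-bin epoch counts
#' and leaving every waveform untouched. Repeating this and re-averaging
#' yields the null distribution of any between-bin contrast. Epochs must
#' belong to exactly one bin.
#'
#' @param ep An `erp_epochs` whose epochs each carry exactly one bin.
#' @param seed Integer seed; the same seed reproduces the same permutation.
#' @return An `erp_epochs` with permuted bin labels.
#' @export
permute_bin_labels <- function(ep, seed) {
  stopifnot(inherits(ep, "erp_epochs"))
  if (any(lengths(ep$epochs$bins) != 1L))
    stop("permutation requires exactly one bin per epoch", call. = FALSE)
  labs <- unlist(ep$epochs$bins)
  perm <- with_seed(seed, sample(labs))
  ep$epochs$bins <- as.list(perm)
  append_history(ep, sprintf("permute_bin_labels(x, seed = %d)", as.integer(seed)))
}
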