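#' Detector specifications
#'
#' Each common EEG artifact has a distinctive morphology, and each detector
#' here is tailored to one of them:
#'
#' * `simple_threshold` — any sample outside `[vmin, vmax]` (absolute voltage;
#'   the classic, crude criterion).
#' * `moving_p2p` — maximum peak-to-peak amplitude (`max - min`) over a moving
#'   window; robust against slow drifts, the workhorse for eyeblinks.
#' * `step_like` — maximum over moving windows of
#'   `|mean(second half) - mean(first half)|`, i.e. the cross-covariance of
#'   the data with a step template scaled by the half-window length; tailored
#'   to saccadic eye movements, which are sudden step-like shifts.
#' * `flatline` — a run of at least `min_duration_ms` in which the voltage
#'   range stays within `threshold` (tolerance); detects amplifier/ADC
#'   blocking, which produces nearly (but not perfectly) constant voltage.
#' * `sample_diff` — maximum absolute sample-to-sample difference; catches
#'   single-sample spikes and discontinuities.
#'
#' Window positions advance by `step_ms` and always include a final position
#' flush with the end of the test window, so there is no blind spot at the
#' epoch edge. All detectors except `simple_threshold` are translation
#' invariant (adding a constant changes no decision).
#'
#' @param algorithm One of the five detector names above.
#' @param channels Integer indices of the channels to test.
#' @param test_window Numeric `(start, end)` in ms within the epoch; default
#'   the whole epoch.
#' @param threshold Positive scalar in microvolts: the detection threshold, or
#'   the tolerance for `flatline`; for `simple_threshold` a `(vmin, vmax)`
#'   pair is also accepted (a single value `v` means `c(-v, v)`).
#' @param width_ms,step_ms Moving-window width and step (moving_p2p,
#'   step_like).
#' @param min_duration_ms Minimum run length for `flatline`.
#' @param flag Which artifact flag (2-8) to set in addition to the master
#'   flag 1.
#' @return A `detector_spec`.
#' @export
detector_spec <- function(algorithm = c("simple_threshold", "moving_p2p", "step_like",
                                        "flatline", "sample_diff"),
                          channels, test_window = NULL, threshold,
                          width_ms = 200, step_ms = 20, min_duration_ms = 200,
                          flag = 2L) {
  algorithm <- match.arg(algorithm)
  if (any(threshold <= 0) && algorithm != "simple_threshold")
    stop("threshold must be positive", call. = FALSE)
  if (flag < 2L || flag > 8L) stop("flag must be 2..8 (flag 1 is reserved)", call. = FALSE)
  if (step_ms <= 0) stop("step_ms must be positive", call. = FALSE)
  structure(list(algorithm = algorithm, channels = channels,
                 test_window = test_window, threshold = threshold,
                 width_ms = width_ms, step_ms = step_ms,
                 min_duration_ms = min_duration_ms, flag = as.integer(flag)),
            class = "detector_spec")
}

# moving-window start offsets (0-based) over n samples for width w, step s;
# includes a final partial-fit position flush with the window end
window_starts <- function(n, w, s) {
  if (w > n) stop("window width exceeds the tested segment", call. = FALSE)
  starts <- seq(0L, n - w, by = s)
  if (starts[length(starts)] != n - w) starts <- c(starts, n - w)
  starts
}

# detector statistic for one single-channel trace (already windowed)
detector_statistic <- function(x, spec, srate) {
  w <- max(2L, round(spec$width_ms * srate / 1000))
  s <- max(1L, round(spec$step_ms * srate / 1000))
  switch(spec$algorithm,
    moving_p2p = {
      max(vapply(window_starts(length(x), w, s), function(s0) {
        seg <- x[(s0 + 1L):(s0 + w)]
        max(seg) - min(seg)
      }, 0))
    },
    step_like = {
      half <- w %/% 2L
      max(vapply(window_starts(length(x), 2L * half, s), function(s0) {
        abs(mean(x[(s0 + half + 1L):(s0 + 2L * half)]) -
            mean(x[(s0 + 1L):(s0 + half)]))
      }, 0))
    },
    sample_diff = if (length(x) < 2L) 0 else max(abs(diff(x))),
    stop("no scalar statistic for ", spec$algorithm, call. = FALSE))
}

detector_decision <- function(x, spec, srate) {
  switch(spec$algorithm,
    simple_threshold = {
      lim <- if (length(spec$threshold) == 2L) spec$threshold
             else c(-abs(spec$threshold), abs(spec$threshold))
      any(x < lim[1] | x > lim[2])
    },
    flatline = {
      run <- max(2L, round(spec$min_duration_ms * srate / 1000))
      if (run > length(x)) return(FALSE)
      any(vapply(window_starts(length(x), run, 1L), function(s0) {
        seg <- x[(s0 + 1L):(s0 + run)]
        (max(seg) - min(seg)) <= spec$threshold
      }, TRUE))
    },
    detector_statistic(x, spec, srate) > spec$threshold)
}

#' Run an artifact detector over epoched EEG
#'
#' Epochs containing artifacts are marked, never deleted: for every epoch and
#' tested channel whose detector statistic exceeds the threshold, the
#' per-channel mark, the master artifact flag 1 and the detector's own flag
#' are set on the epoch, and the same flags are mirrored onto the home event
#' in the event list. Marked epochs can then be excluded (or isolated) at
#' averaging time.
#'
#' @param ep An `erp_epochs`.
#' @param spec A [detector_spec()].
#' @return The flagged `erp_epochs`.
#' @export
detect_artifacts <- function(ep, spec) {
  stopifnot(inherits(ep, "erp_epochs"), inherits(spec, "detector_spec"))
  if (any(spec$channels < 1L | spec$channels > dim(ep$data)[2]))
    stop("detector channel index out of range", call. = FALSE)
  tw <- if (is.null(spec$test_window)) c(ep$tmin, ep$tmax) else spec$test_window
  idx <- window_sample_idx(ep, tw[1], tw[2], what = "test window")
  for (e in seq_len(dim(ep$data)[1])) {
    hit <- FALSE
    for (ch in spec$channels) {
      if (detector_decision(ep$data[e, ch, idx], spec, ep$srate)) {
        ep$chan_marks[e, ch] <- TRUE
        hit <- TRUE
      }
    }
    if (hit) {
      ep$flags[e, 1L] <- TRUE
      ep$flags[e, spec$flag] <- TRUE
      item <- ep$epochs$item[e]
      row <- match(item, ep$events$events$item)
      if (!is.na(row)) {
        f <- ep$events$events$artifact_flags[row]
        f <- flag_set(f, 1L); f <- flag_set(f, spec$flag)
        ep$events$events$artifact_flags[row] <- f
      }
    }
  }
  append_history(ep, sprintf(
    'detect_artifacts(x, detector_spec(algorithm = "%s", channels = c(%s), test_window = c(%.6g, %.6g), threshold = c(%s), width_ms = %.6g, step_ms = %.6g, min_duration_ms = %.6g, flag = %d))',
    spec$algorithm, paste(spec$channels, collapse = ","), tw[1], tw[2],
    paste(spec$threshold, collapse = ","), spec$width_ms, spec$step_ms,
    spec$min_duration_ms, spec$flag))
}

#' Clear artifact flags
#'
#' Clears the listed flags (1-8) on all epochs and on the mirrored events.
#'
#' @param ep An `erp_epochs`.
#' @param flags Integer set within 1..8.
#' @return The cleared `erp_epochs`.
#' @export
clear_flags <- function(ep, flags = 1:8) {
  stopifnot(inherits(ep, "erp_epochs"), all(flags %in% 1:8))
  ep$flags[, flags] <- FALSE
  # per-channel marks hang off the master flag
  if (1L %in% flags) ep$chan_marks[] <- FALSE
  for (row in seq_len(n_events(ep$events))) {
    f <- ep$events$events$artifact_flags[row]
    for (k in flags) f <- flag_set(f, k, FALSE)
    ep$events$events$artifact_flags[row] <- f
  }
  append_history(ep, sprintf("clear_flags(x, flags = c(%s))", paste(flags, collapse = ",")))
}

#' Delete gross-artifact segments from continuous EEG
#'
#' Scans the continuous recording with a moving peak-to-peak window on the
#' given channels; windows exceeding the threshold are expanded by `pad_ms`
#' on each side, overlapping spans are merged, and the merged spans are cut
#' out of the recording. A boundary marker is inserted at every splice (so
#' later epoching never spans a cut), and events inside deleted spans are
#' removed. Intended for the huge idiosyncratic artifacts (subject stretching
#' during a break) that would otherwise poison downstream processing.
#'
#' @param eeg An `erp_continuous`.
#' @param channels Channel indices to scan.
#' @param threshold Peak-to-peak threshold in microvolts.
#' @param width_ms Moving-window width in ms.
#' @param pad_ms Padding added to each side of an exceeding window.
#' @return The spliced `erp_continuous`; the number of deleted segments is
#'   stored as `n_deleted_segments`.
#' @export
reject_continuous <- function(eeg, channels, threshold, width_ms, pad_ms = 0) {
  stopifnot(inherits(eeg, "erp_continuous"), threshold > 0)
  fs <- eeg$srate
  ns <- ncol(eeg$data)
  w <- max(2L, round(width_ms * fs / 1000))
  if (w > ns) stop("window width exceeds the recording", call. = FALSE)
  pad <- round(pad_ms * fs / 1000)
  step <- max(1L, w %/% 2L)
  spans <- list()
  for (ch in channels) {
    x <- eeg$data[ch, ]
    for (s0 in window_starts(ns, w, step)) {
      seg <- x[(s0 + 1L):(s0 + w)]
      if (max(seg) - min(seg) > threshold)
        spans[[length(spans) + 1L]] <- c(max(0L, s0 - pad), min(ns, s0 + w + pad))
    }
  }
  if (!length(spans)) {
    return(append_history(eeg, sprintf(
      "reject_continuous(x, channels = c(%s), threshold = %.6g, width_ms = %.6g, pad_ms = %.6g)",
      paste(channels, collapse = ","), threshold, width_ms, pad_ms)))
  }
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    else merged[[length(merged) + 1L]] <- m[i, ]
  }
  keep <- rep(TRUE, ns)
  for (sp in merged) if (sp[2] > sp[1]) keep[(sp[1] + 1L):sp[2]] <- FALSE
  # map old 0-based sample index -> new index (samples kept before it)
  new_index <- cumsum(keep)   # new count up to old sample i (1-based)
  eeg$data <- eeg$data[, keep, drop = FALSE]
  # splice boundaries: new index of each deleted span start
  splices <- vapply(merged, function(sp) {
    if (sp[1] == 0L) 0L else as.integer(new_index[sp[1]])
  }, 0L)
  old_bnd <- vapply(eeg$boundaries, function(b) {
    if (b == 0L) 0L else as.integer(new_index[b])
  }, 0L)
  eeg$boundaries <- sort(unique(c(old_bnd, splices)))
  # events inside deleted spans are removed; survivors get remapped onsets
  e <- eeg$events$events
  if (nrow(e)) {
    smp <- round(e$onset * fs)
    alive <- keep[pmin(smp + 1L, ns)]
    e <- e[alive, ]
    if (nrow(e)) {
      smp <- round(e$onset * fs)
      e$onset <- (new_index[smp + 1L] - 1L) / fs
      e$item <- seq_len(nrow(e))
    }
    eeg$events <- eventlist(e, srate = fs)
  }
  eeg$n_deleted_segments <- length(merged)
  validate_continuous(eeg)
  append_history(eeg, sprintf(
    "reject_continuous(x, channels = c(%s), threshold = %.6g, width_ms = %.6g, pad_ms = %.6g)",
    paste(channels, collapse = ","), threshold, width_ms, pad_ms))
}

#' Rejection report
#'
#' Summarizes artifact marking per bin and overall: total epochs, flagged
#' epochs, and the flagged proportion, plus per-channel mark counts. The
#' overall exclusion indicator says whether the subject's rejection proportion
#' exceeds the laboratory's preset criterion; the default criterion of 25%
#' reflects the common policy of excluding subjects with more than a quarter
#' of trials rejected, decided before looking at the data so that post hoc
#' subject exclusion cannot inflate the Type I error rate.
#'
#' @param ep An `erp_epochs` after artifact detection.
#' @param exclusion_threshold Proportion above which the subject should be
#'   excluded (default 0.25).
#' @return A list with tibbles `by_bin`, `by_channel`, and scalars `n_total`,
#'   `n_flagged`, `proportion`, `exclude_subject`.
#' @export
rejection_report <- function(ep, exclusion_threshold = 0.25) {
  stopifnot(inherits(ep, "erp_epochs"))
  bins <- sort(unique(unlist(ep$epochs$bins)))
  flagged <- ep$flags[, 1]
  by_bin <- dplyr::bind_rows(lapply(bins, function(b) {
    in_bin <- vapply(ep$epochs$bins, function(x) b %in% x, TRUE)
    tibble::tibble(bin = b, n_total = sum(in_bin),
                   n_flagged = sum(in_bin & flagged),
                   proportion = sum(in_bin & flagged) / max(1L, sum(in_bin)))
  }))
  by_channel <- tibble::tibble(channel = ep$chan_labels,
                               n_marks = colSums(ep$chan_marks))
  n_total <- dim(ep$data)[1]
  n_flagged <- sum(flagged)
  prop <- n_flagged / n_total
  list(by_bin = by_bin, by_channel = by_channel,
       n_total = n_total, n_flagged = n_flagged, proportion = prop,
       exclude_subject = prop > exclusion_threshold)
}

#' Insert event codes at detected EEG features
#'
#' Slides a detector (`moving_p2p`, `step_like` or `simple_threshold`) over a
#' channel of the continuous recording and inserts one event with
#' `new_code` at the onset sample of each maximal supra-threshold excursion
#' (overlapping exceeding windows are merged into one excursion). The new
#' events are sorted into the event list by onset; they can then serve as
#' time-locking events, e.g. for blink- or saccade-locked averages.
#'
#' @param eeg An `erp_continuous`.
#' @param channel Channel index to scan.
#' @param spec A [detector_spec()] with one of the three algorithms above.
#' @param new_code Integer code for the inserted events.
#' @param label Label for the inserted events.
#' @return The `erp_continuous` with inserted events.
#' @export
insert_feature_events <- function(eeg, channel, spec, new_code, label = "feature") {
  stopifnot(inherits(eeg, "erp_continuous"), inherits(spec, "detector_spec"))
  if (!spec$algorithm %in% c("moving_p2p", "step_like", "simple_threshold"))
    stop("continuous feature detection supports moving_p2p, step_like, simple_threshold",
         call. = FALSE)
  fs <- eeg$srate
  x <- eeg$data[channel, ]
  ns <- length(x)
  w <- max(2L, round(spec$width_ms * fs / 1000))
  s <- max(1L, round(spec$step_ms * fs / 1000))
  starts <- window_starts(ns, w, s)
  sub <- detector_spec(spec$algorithm, channels = channel, threshold = spec$threshold,
                       width_ms = spec$width_ms, step_ms = spec$step_ms,
                       flag = spec$flag)
  hit <- vapply(starts, function(s0)
    detector_decision(x[(s0 + 1L):(s0 + w)], sub, fs), TRUE)
  if (!any(hit)) {
    return(append_history(eeg, sprintf(
      'insert_feature_events(x, channel = %d, spec = detector_spec("%s", channels = %d, threshold = %.6g, width_ms = %.6g, step_ms = %.6g), new_code = %d, label = "%s")',
      channel, spec$algorithm, channel, spec$threshold[1], spec$width_ms,
      spec$step_ms, new_code, label)))
  }
  # merge overlapping exceeding windows into maximal excursions
  spans <- cbind(starts[hit], starts[hit] + w)
  merged <- list(spans[1, ])
  for (i in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], spans[i, 2]))
    else merged[[length(merged) + 1L]] <- spans[i, ]
  }
  codes_in_use <- unique(eeg$events$events$code)
  if (new_code %in% codes_in_use)
    warning("new_code ", new_code, " collides with an existing event code", call. = FALSE)
  e <- eeg$events$events
  add <- tibble::tibble(
    item = 0L, code = as.integer(new_code), label = label,
    onset = vapply(merged, function(sp) sp[1] / fs, 0),
    duration = 0, enabled = TRUE, bins = list(integer()),
    artifact_flags = strrep("0", 8), user_flags = strrep("0", 8)
  )
  eeg$events <- eventlist(dplyr::bind_rows(e, add), srate = fs)
  append_history(eeg, sprintf(
    'insert_feature_events(x, channel = %d, spec = detector_spec("%s", channels = %d, threshold = %.6g, width_ms = %.6g, step_ms = %.6g), new_code = %d, label = "%s")',
    channel, spec$algorithm, channel, spec$threshold[1], spec$width_ms,
    spec$step_ms, new_code, label))
}
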