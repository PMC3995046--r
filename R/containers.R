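#' Continuous EEG recordings
#'
#' Holds a channels-by-samples matrix of voltages in microvolts together with
#' the sampling rate, channel labels, the event list, boundary markers (sample
#' indices where the recording is discontinuous, e.g. block starts or splices
#' left by continuous artifact deletion) and a replayable history of every
#' operation applied.
#'
#' Sample indexing is 0-based internally: an event at `onset` seconds maps to
#' sample `round(onset * srate)`.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param srate Sampling rate in Hz.
#' @param chan_labels Character vector of unique channel labels.
#' @param events An `erp_eventlist` (default: empty).
#' @param boundaries Sorted integer vector of 0-based sample indices at which a
#'   new, discontinuous block starts.
#' @return An object of class `erp_continuous`.
#' @export
continuous_eeg <- function(data, srate, chan_labels = NULL, events = NULL,
                           boundaries = integer()) {
  data <- as.matrix(data)
  if (is.null(chan_labels)) chan_labels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(events)) events <- eventlist(NULL, srate = srate)
  x <- structure(list(
    data = data, srate = srate, chan_labels = chan_labels,
    events = events, boundaries = sort(unique(as.integer(boundaries))),
    history = character()
  ), class = "erp_continuous")
  validate_continuous(x)
  x
}

validate_continuous <- function(x) {
  stopifnot(x$srate > 0)
  if (length(x$chan_labels) != nrow(x$data))
    stop("channel label count must equal channel count", call. = FALSE)
  if (anyDuplicated(x$chan_labels))
    stop("channel labels must be unique", call. = FALSE)
  ns <- ncol(x$data)
  if (n_events(x$events)) {
    smp <- round(x$events$events$onset * x$srate)
    if (any(smp < 0 | smp >= ns))
      stop("event onset outside recording", call. = FALSE)
  }
  if (length(x$boundaries) && (min(x$boundaries) < 0 || max(x$boundaries) > ns))
    stop("boundary index outside recording", call. = FALSE)
  invisible(x)
}

#' Epoched EEG
#'
#' Fixed-length segments cut around time-locking events. `data` is an
#' epochs x channels x samples array; the epoch table records, per epoch, the
#' item index of its home event and the bins it belongs to; `flags` is an
#' epochs x 8 logical matrix of artifact flags (flag 1 is the master artifact
#' flag) and `chan_marks` an epochs x channels matrix of per-channel detector
#' marks. The mirror event list is carried so detectors can flag home events.
#'
#' @param data epochs x channels x samples array (microvolts).
#' @param srate Sampling rate in Hz.
#' @param tmin,tmax Epoch window in ms relative to the time-locking event;
#'   the window is half-open `[tmin, tmax)`.
#' @param chan_labels Channel labels.
#' @param epochs Tibble with columns `epoch`, `item`, `bins` (list column).
#' @param events Mirror `erp_eventlist`.
#' @param flags,chan_marks Optional logical matrices (default all `FALSE`).
#' @return An object of class `erp_epochs`.
#' @export
epoched_eeg <- function(data, srate, tmin, tmax, chan_labels, epochs, events,
                        flags = NULL, chan_marks = NULL) {
  n_ep <- dim(data)[1]
  n_expect <- round((tmax - tmin) * srate / 1000)
  if (dim(data)[3] != n_expect)
    stop("sample count does not match the epoch window", call. = FALSE)
  if (tmin > 0 || tmax <= 0)
    stop("time zero must lie inside [tmin, tmax)", call. = FALSE)
  if (is.null(flags)) flags <- matrix(FALSE, n_ep, 8L)
  if (is.null(chan_marks)) chan_marks <- matrix(FALSE, n_ep, dim(data)[2])
  if (any(lengths(epochs$bins) == 0L))
    stop("every epoch must belong to at least one bin", call. = FALSE)
  structure(list(
    data = data, srate = srate, tmin = tmin, tmax = tmax,
    chan_labels = chan_labels, epochs = tibble::as_tibble(epochs),
    flags = flags, chan_marks = chan_marks, events = events,
    history = character()
  ), class = "erp_epochs")
}

#' Averaged ERP sets
#'
#' Stores one averaged waveform per bin and channel (bins x channels x samples
#' array, microvolts) plus per-bin trial accounting: the number of accepted
#' epochs, the total rejected, and the rejected count broken down by artifact
#' flag. All bins of a set share the same channel and time axes, so a whole
#' experiment's conditions live in one object.
#'
#' @param data bins x channels x samples array (microvolts).
#' @param srate Sampling rate in Hz.
#' @param tmin,tmax Epoch window in ms (half-open).
#' @param bin_labels,chan_labels Axis labels.
#' @param counts Tibble with columns `bin`, `n_accepted`, `n_rejected`
#'   (defaults to zeros, meaning unknown).
#' @param rejected_by_flag bins x 8 integer matrix (defaults to zeros).
#' @param subject Subject identifier.
#' @return An object of class `erp_set`.
#' @export
erp_set <- function(data, srate, tmin, tmax, bin_labels = NULL,
                    chan_labels = NULL, counts = NULL,
                    rejected_by_flag = NULL, subject = "") {
  nb <- dim(data)[1]
  if (is.null(bin_labels)) bin_labels <- paste0("bin", seq_len(nb))
  if (is.null(chan_labels)) chan_labels <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(counts))
    counts <- tibble::tibble(bin = seq_len(nb), n_accepted = 0L, n_rejected = 0L)
  if (is.null(rejected_by_flag))
    rejected_by_flag <- matrix(0L, nb, 8L)
  if (any(counts$n_accepted < 0) || any(counts$n_rejected < 0))
    stop("trial counts must be non-negative", call. = FALSE)
  structure(list(
    data = data, srate = srate, tmin = tmin, tmax = tmax,
    bin_labels = bin_labels, chan_labels = chan_labels,
    counts = tibble::as_tibble(counts), rejected_by_flag = rejected_by_flag,
    subject = subject, history = character()
  ), class = "erp_set")
}

#' @export
print.erp_continuous <- function(x, ...) {
  cat(sprintf("<erp_continuous> %d channels x %d samples @ %g Hz (%.1f s), %d events, %d boundaries\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              n_events(x$events), length(x$boundaries)))
  invisible(x)
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> %d epochs x %d channels x %d samples, window [%g, %g) ms @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$tmin, x$tmax, x$srate))
  cat(sprintf("  flagged (artifact flag 1): %d\n", sum(x$flags[, 1])))
  invisible(x)
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> %d bins x %d channels x %d samples, window [%g, %g) ms @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$tmin, x$tmax, x$srate))
  print(x$counts)
  invisible(x)
}

#' Time axis of an epoch-shaped object, in ms
#' @param x An `erp_epochs` or `erp_set`.
#' @return Numeric vector of sample times (ms), `tmin + k * 1000 / srate`.
#' @export
time_axis <- function(x) {
  n <- dim(x$data)[length(dim(x$data))]
  x$tmin + (seq_len(n) - 1L) * 1000 / x$srate
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.erp_set <- function(x, ...) {
  tm <- time_axis(x)
  d <- dim(x$data)
  tibble::tibble(
    bin = rep(seq_len(d[1]), each = d[2] * d[3]),
    bin_label = rep(x$bin_labels, each = d[2] * d[3]),
    channel = rep(rep(x$chan_labels, each = d[3]), times = d[1]),
    time = rep(tm, times = d[1] * d[2]),
    amplitude = as.vector(aperm(x$data, c(3, 2, 1)))
  )
}

#' Append a command to an object's history
#'
#' Every public operation records a canonical, replayable command string in the
#' object it returns; `append_history()` is the single point where this
#' happens. Command strings are R expressions in which the processed object is
#' named `x`, so a recorded pipeline can be re-run with [replay_history()].
#'
#' @param obj An `erp_continuous`, `erp_epochs` or `erp_set`.
#' @param command Character scalar, a replayable command.
#' @return The object with `history` grown by one entry.
#' @export
append_history <- function(obj, command) {
  stopifnot(is.character(command), length(command) == 1L)
  obj$history <- c(obj$history, command)
  obj
}

#' Replay a recorded history on an input object
#'
#' Evaluates each history command (expressions over the name `x`) in turn,
#' starting from `input`. For deterministic operations this reproduces the
#' processed object bit for bit.
#'
#' @param input The original object the history was recorded from.
#' @param history Character vector of commands (e.g. `processed$history`).
#' @return The re-processed object.
#' @export
replay_history <- function(input, history) {
  x <- input
  env <- new.env(parent = asNamespace("erpkit"))
  for (cmd in history) {
    assign("x", x, envir = env)
    x <- eval(parse(text = cmd)[[1]], env)
  }
  x
}

# shared guard: all public maths must keep the data finite
assert_finite <- function(obj, what = "data") {
  if (!all(is.finite(obj$data)))
    stop("non-finite values produced in ", what, call. = FALSE)
  obj
}
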