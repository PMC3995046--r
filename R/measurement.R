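#' Cubic-spline upsampling of a waveform
#'
#' Latency algorithms are limited by the sampling grid — there may be no
#' sample at exactly 50% of the peak voltage. Interpolating the waveform onto
#' a denser grid before measuring removes most of this quantization error,
#' which matters especially for jackknifed measurements where other error
#' sources are already tiny.
#'
#' @param wave Numeric waveform (at least 4 samples).
#' @param srate Sampling rate in Hz.
#' @param factor Integer >= 1; `1` returns the input unchanged.
#' @return List with `wave` (length `(n-1)*factor + 1`, original samples
#'   reproduced exactly) and `srate` (`srate * factor`).
#' @export
upsample_spline <- function(wave, srate, factor = 1L) {
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(list(wave = wave, srate = srate))
  n <- length(wave)
  if (n < 4L) stop("need at least 4 samples for spline interpolation", call. = FALSE)
  xi <- seq(1, n, by = 1 / factor)
  list(wave = stats::spline(seq_len(n), wave, xout = xi, method = "fmm")$y,
       srate = srate * factor)
}

# pull one (bin, channel) waveform, with optional spline upsampling;
# returns wave, its sample times in ms, and Δt
get_waveform <- function(erp, bin, chan, interp_factor = 1L) {
  stopifnot(inherits(erp, "erp_set"))
  b <- resolve_bin(erp, bin)
  ch <- resolve_chan(erp, chan)
  wave <- erp$data[b, ch, ]
  tm <- time_axis(erp)
  if (interp_factor > 1L) {
    up <- upsample_spline(wave, erp$srate, interp_factor)
    wave <- up$wave
    tm <- tm[1] + (seq_along(wave) - 1L) * 1000 / up$srate
  }
  list(wave = wave, tm = tm, dt = tm[2] - tm[1])
}

resolve_bin <- function(erp, bin) {
  if (is.character(bin)) bin <- match(bin, erp$bin_labels)
  if (is.na(bin) || bin < 1L || bin > dim(erp$data)[1])
    stop("no such bin", call. = FALSE)
  bin
}

resolve_chan <- function(erp, chan) {
  if (is.character(chan)) {
    i <- match(chan, erp$chan_labels)
    if (is.na(i)) stop("no such channel: ", chan, call. = FALSE)
    return(i)
  }
  if (chan < 1L || chan > dim(erp$data)[2]) stop("no such channel", call. = FALSE)
  chan
}

measure_window <- function(tm, start, end, tmin, tmax) {
  if (end <= start) stop("window end must exceed start", call. = FALSE)
  if (start < tmin - 1e-9 || end > tmax + 1e-9)
    stop(sprintf("window [%g, %g] outside epoch [%g, %g)", start, end, tmin, tmax),
         call. = FALSE)
  idx <- which(tm >= start - 1e-9 & tm < end - 1e-9)
  if (!length(idx)) stop("window contains no samples", call. = FALSE)
  idx
}

#' Mean amplitude in a window
#'
#' The arithmetic mean voltage over samples whose times lie in
#' `[start, end)` ms: the most robust and widely recommended amplitude
#' measure, linear in the data and therefore unbiased by noise level.
#'
#' @param erp An `erp_set`.
#' @param bin,chan Bin number (or label) and channel index (or label).
#' @param window Numeric `(start, end)` in ms.
#' @return Mean amplitude in microvolts.
#' @export
mean_amplitude <- function(erp, bin, chan, window) {
  g <- get_waveform(erp, bin, chan)
  idx <- measure_window(g$tm, window[1], window[2], erp$tmin, erp$tmax)
  mean(g$wave[idx])
}

area_transform <- function(x, area_mode) {
  switch(area_mode,
    positive = pmax(x, 0),
    negative = -pmin(x, 0),    # returned as a positive magnitude
    rectified = abs(x),
    integral = x,
    stop("unknown area mode: ", area_mode, call. = FALSE))
}

#' Area amplitude in a window
#'
#' The area under the waveform over `[start, end)`, as microvolt-ms:
#' `dt * sum(f(x))` with `f` selected by `area_mode` — the positive region
#' only, the negative region only (returned as a positive magnitude), the
#' rectified sum of both, or the signed integral. Restricting to one polarity
#' lets a broad measurement window capture a component (say the N2) without
#' opposite-polarity neighbors (P2, P3) canceling it.
#'
#' @inheritParams mean_amplitude
#' @param area_mode `"positive"`, `"negative"`, `"rectified"` or
#'   `"integral"`.
#' @return Area in microvolt-milliseconds.
#' @export
area_amplitude <- function(erp, bin, chan, window,
                           area_mode = c("positive", "negative", "rectified", "integral")) {
  area_mode <- match.arg(area_mode)
  g <- get_waveform(erp, bin, chan)
  idx <- measure_window(g$tm, window[1], window[2], erp$tmin, erp$tmax)
  g$dt * sum(area_transform(g$wave[idx], area_mode))
}

#' Peak amplitude and latency, with a local-peak criterion
#'
#' Finds the most extreme sample in the window (maximum for positive
#' polarity, minimum for negative). With `local_points > 0`, a candidate only
#' counts as a peak if it also exceeds (falls below, for negative polarity)
#' the mean of its `local_points` neighbors on each side — neighbors may
#' extend beyond the window but not beyond the epoch. This prevents the
#' rising edge of an adjacent component, clipped at the window border, from
#' being mistaken for a peak. If no sample qualifies, the absolute extreme is
#' returned with a warning. Ties break toward the earliest latency.
#'
#' @inheritParams mean_amplitude
#' @param polarity `"positive"` or `"negative"`.
#' @param local_points Neighborhood half-width in samples; 0 = absolute
#'   extreme.
#' @param interp_factor Spline upsampling factor applied before measuring.
#' @return List with `amplitude` (microvolts), `latency` (ms), and `local`
#'   (`FALSE` if the local criterion failed and the absolute extreme was
#'   used).
#' @export
peak_measure <- function(erp, bin, chan, window,
                         polarity = c("positive", "negative"),
                         local_points = 0L, interp_factor = 1L) {
  polarity <- match.arg(polarity)
  g <- get_waveform(erp, bin, chan, interp_factor)
  idx <- measure_window(g$tm, window[1], window[2], erp$tmin, erp$tmax)
  sgn <- if (polarity == "positive") 1 else -1
  w <- sgn * g$wave
  if (local_points > 0L) {
    ok <- vapply(idx, function(i) {
      lo <- (i - local_points):(i - 1L)
      hi <- (i + 1L):(i + local_points)
      lo <- lo[lo >= 1L]; hi <- hi[hi <= length(w)]
      length(lo) > 0L && length(hi) > 0L &&
        w[i] > mean(w[lo]) && w[i] > mean(w[hi])
    }, TRUE)
    cand <- idx[ok]
    if (!length(cand)) {
      warning("no local peak in window; falling back to the absolute extreme",
              call. = FALSE)
      i <- idx[which.max(w[idx])]
      return(list(amplitude = g$wave[i], latency = g$tm[i], local = FALSE))
    }
    i <- cand[which.max(w[cand])]
  } else {
    i <- idx[which.max(w[idx])]
  }
  list(amplitude = g$wave[i], latency = g$tm[i], local = TRUE)
}

#' Fractional area latency
#'
#' Accumulates the area (under the selected `area_mode`) sample by sample
#' across the window and returns the time at which the cumulative area first
#' reaches `fraction` of the total, linearly interpolated within the
#' straddling sample interval. With a fraction of 0.5 this is the point
#' dividing the area into two equal halves — a highly reliable latency
#' measure directly comparable to a median reaction time; smaller fractions
#' (e.g. 0.2) estimate onset latency, particularly on difference waves.
#'
#' @inheritParams area_amplitude
#' @param fraction In (0, 1); default 0.5.
#' @param interp_factor Spline upsampling factor applied before measuring.
#' @return Latency in ms.
#' @export
fractional_area_latency <- function(erp, bin, chan, window, fraction = 0.5,
                                    area_mode = c("positive", "negative", "rectified", "integral"),
                                    interp_factor = 1L) {
  area_mode <- match.arg(area_mode)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  g <- get_waveform(erp, bin, chan, interp_factor)
  idx <- measure_window(g$tm, window[1], window[2], erp$tmin, erp$tmax)
  f <- area_transform(g$wave[idx], area_mode)
  total <- sum(f) * g$dt
  if (total <= 0) stop("no area to divide in window", call. = FALSE)
  target <- fraction * total
  cum <- cumsum(f) * g$dt          # area accrued by the END of each sample interval
  k <- which(cum >= target - 1e-12)[1]
  before <- if (k == 1L) 0 else cum[k - 1L]
  within <- f[k] * g$dt
  fracdt <- if (within > 0) (target - before) / within else 0
  g$tm[idx[k]] + fracdt * g$dt
}

#' Fractional peak latency
#'
#' Finds the peak (see [peak_measure()]) and scans backward in time to the
#' first sample at or beyond which the voltage has dropped to `fraction` of
#' the peak amplitude, returning the linearly interpolated crossing time. The
#' 50% point on the leading edge is an accurate and robust onset estimator
#' for averaged waveforms, where trial-to-trial latency jitter pushes the
#' nominal onset earlier than any single trial's. Returns `NA` with a warning
#' if the criterion is never met before the epoch start.
#'
#' @inheritParams peak_measure
#' @param fraction In (0, 1); default 0.5.
#' @return Latency in ms, or `NA` if the waveform never crosses the
#'   criterion.
#' @export
fractional_peak_latency <- function(erp, bin, chan, window, fraction = 0.5,
                                    polarity = c("positive", "negative"),
                                    local_points = 0L, interp_factor = 1L) {
  polarity <- match.arg(polarity)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  g <- get_waveform(erp, bin, chan, interp_factor)
  idx <- measure_window(g$tm, window[1], window[2], erp$tmin, erp$tmax)
  sgn <- if (polarity == "positive") 1 else -1
  w <- sgn * g$wave
  # locate the peak within the window (same rules as peak_measure)
  if (local_points > 0L) {
    ok <- vapply(idx, function(i) {
      lo <- (i - local_points):(i - 1L); hi <- (i + 1L):(i + local_points)
      lo <- lo[lo >= 1L]; hi <- hi[hi <= length(w)]
      length(lo) > 0L && length(hi) > 0L && w[i] > mean(w[lo]) && w[i] > mean(w[hi])
    }, TRUE)
    cand <- idx[ok]
    ipk <- if (length(cand)) cand[which.max(w[cand])] else idx[which.max(w[idx])]
  } else {
    ipk <- idx[which.max(w[idx])]
  }
  crit <- fraction * w[ipk]
  i <- ipk
  while (i >= 1L && w[i] > crit) i <- i - 1L
  if (i < 1L) {
    warning("voltage never reaches ", fraction, " of the peak before the epoch start",
            call. = FALSE)
    return(NA_real_)
  }
  # linear crossing between samples i and i+1
  if (w[i + 1L] == w[i]) return(g$tm[i])
  frac <- (crit - w[i]) / (w[i + 1L] - w[i])
  g$tm[i] + frac * g$dt
}

#' Measure many ERP sets into a table
#'
#' Applies one measurement to every (ERP set, bin, channel) combination and
#' writes a tab-separated table. The wide layout has one row per ERP set and
#' one `bin<k>_<chanlabel>` column per measurement, convenient for
#' statistical packages; the long layout has one row per measured value with
#' `erpset`, `bin`, `bin_label`, `channel`, `value` columns, convenient for
#' pivot tables. Missing values are written as `NA`.
#'
#' @param erps List of `erp_set`s with identical axes.
#' @param algorithm One of `"mean_amp"`, `"area_amp"`, `"peak_amp"`,
#'   `"peak_lat"`, `"frac_area_lat"`, `"frac_peak_lat"`.
#' @param window Measurement window `(start, end)` ms.
#' @param bins,channels Index vectors (defaults: all).
#' @param polarity,area_mode,fraction,local_points,interp_factor Algorithm
#'   parameters, as in the individual measurement functions.
#' @param layout `"wide"` or `"long"`.
#' @param path Optional output file for the tab-separated table.
#' @return A tibble in the requested layout.
#' @export
measure_erps <- function(erps, algorithm = c("mean_amp", "area_amp", "peak_amp",
                                             "peak_lat", "frac_area_lat", "frac_peak_lat"),
                         window, bins = NULL, channels = NULL,
                         polarity = "positive", area_mode = "positive",
                         fraction = 0.5, local_points = 0L, interp_factor = 1L,
                         layout = c("wide", "long"), path = NULL) {
  algorithm <- match.arg(algorithm)
  layout <- match.arg(layout)
  if (inherits(erps, "erp_set")) erps <- list(erps)
  check_erp_axes(erps, min_n = 1L)
  ref <- erps[[1]]
  if (is.null(bins)) bins <- seq_len(dim(ref$data)[1])
  if (is.null(channels)) channels <- seq_len(dim(ref$data)[2])
  one <- function(erp, b, ch) {
    tryCatch(switch(algorithm,
      mean_amp = mean_amplitude(erp, b, ch, window),
      area_amp = area_amplitude(erp, b, ch, window, area_mode),
      peak_amp = peak_measure(erp, b, ch, window, polarity, local_points,
                              interp_factor)$amplitude,
      peak_lat = peak_measure(erp, b, ch, window, polarity, local_points,
                              interp_factor)$latency,
      frac_area_lat = fractional_area_latency(erp, b, ch, window, fraction,
                                              area_mode, interp_factor),
      frac_peak_lat = fractional_peak_latency(erp, b, ch, window, fraction,
                                              polarity, local_points, interp_factor)),
      error = function(e) NA_real_)
  }
  grid <- expand.grid(channel = channels, bin = bins, erpset = seq_along(erps))
  long <- tibble::tibble(
    erpset = grid$erpset,
    subject = vapply(grid$erpset, function(i) {
      s <- erps[[i]]$subject
      if (nzchar(s)) s else as.character(i)
    }, ""),
    bin = grid$bin,
    bin_label = ref$bin_labels[grid$bin],
    channel = ref$chan_labels[grid$channel],
    value = mapply(function(i, b, ch) suppressWarnings(one(erps[[i]], b, ch)),
                   grid$erpset, grid$bin, grid$channel)
  )
  out <- if (layout == "long") long else {
    long$column <- paste0("bin", long$bin, "_", long$channel)
    tidyr::pivot_wider(long[, c("erpset", "subject", "column", "value")],
                       names_from = "column", values_from = "value")
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  out
}

#' Waveforms with their measured values, for visual verification
#'
#' Single-subject waveforms vary widely, so a measurement should be checked
#' against each waveform it came from. Returns, per (ERP set, bin, channel),
#' the full waveform samples alongside the measured value, ready for
#' plotting the measure superimposed on the waveform.
#'
#' @inheritParams measure_erps
#' @return A tibble with one row per waveform sample, carrying `value`.
#' @export
measure_viewer_data <- function(erps, algorithm, window, bins = NULL,
                                channels = NULL, ...) {
  if (inherits(erps, "erp_set")) erps <- list(erps)
  meas <- measure_erps(erps, algorithm, window, bins = bins, channels = channels,
                       layout = "long", ...)
  waves <- dplyr::bind_rows(lapply(seq_along(erps), function(i) {
    w <- as_tibble(erps[[i]])
    w$erpset <- i
    w
  }))
  dplyr::left_join(waves, meas[, c("erpset", "bin", "channel", "value")],
                   by = c("erpset", "bin", "channel")) |>
    dplyr::filter(!is.na(.data$value))
}
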