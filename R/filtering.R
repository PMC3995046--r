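#' Zero-phase filter specifications
#'
#' Filters are specified by their *half-amplitude* cutoff — the frequency at
#' which the overall (forward-backward) amplitude response is attenuated by
#' 50%, i.e. 6.02 dB — and, for Butterworth designs, by the asymptotic
#' stopband roll-off in dB/octave. These are the two numbers that should be
#' reported in a paper; note the half-amplitude cutoff differs from the
#' half-power (3.01 dB) cutoff, see [half_power_from_half_amp()].
#'
#' The roll-off names the slope of the overall two-pass response: an order-n
#' Butterworth applied forward and backward falls off at 12n dB/octave, so
#' the supported settings 12/24/36/48 map to orders 1-4. Because the single
#' forward pass of a Butterworth has its half-power point at the design
#' cutoff, the forward-backward composite — whose amplitude is the squared
#' single-pass magnitude, `1/(1 + (f/fc)^(2n))` for a low-pass — is exactly
#' half-amplitude there: the requested cutoff is realized without any
#' correction factor.
#'
#' @param mode `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @param half_amp Half-amplitude cutoff in Hz (two values, low then high,
#'   for bandpass).
#' @param kind `"butterworth"` (default) or `"fir"` (windowed-sinc, Hamming).
#' @param rolloff Butterworth roll-off of the overall response in dB/octave:
#'   12, 24, 36 or 48.
#' @param fir_order Even FIR order (number of taps minus one).
#' @param remove_dc Subtract each segment's mean before filtering? Advisable
#'   for DC-coupled recordings with large offsets; not usually appropriate
#'   for baseline-corrected data.
#' @param per_block Filter each trial block (between boundary markers)
#'   separately? Avoids smearing DC steps at block gaps across the data.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(mode = c("lowpass", "highpass", "bandpass"),
                        half_amp, kind = c("butterworth", "fir"),
                        rolloff = 12, fir_order = 100L,
                        remove_dc = FALSE, per_block = FALSE) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (mode == "bandpass") {
    if (length(half_amp) != 2L || half_amp[1] >= half_amp[2])
      stop("bandpass needs half_amp = c(low, high) with low < high", call. = FALSE)
  } else if (length(half_amp) != 1L) {
    stop(mode, " needs a single half-amplitude cutoff", call. = FALSE)
  }
  if (any(half_amp <= 0)) stop("cutoffs must be positive", call. = FALSE)
  if (kind == "butterworth" && !rolloff %in% c(12, 24, 36, 48))
    stop("supported roll-offs: 12, 24, 36, 48 dB/octave", call. = FALSE)
  if (kind == "fir" && (fir_order < 2L || fir_order %% 2L != 0L))
    stop("fir_order must be a positive even integer", call. = FALSE)
  structure(list(mode = mode, half_amp = half_amp, kind = kind,
                 rolloff = rolloff, fir_order = as.integer(fir_order),
                 remove_dc = isTRUE(remove_dc), per_block = isTRUE(per_block)),
            class = "filter_spec")
}

#' Design a zero-phase filter for a sampling rate
#'
#' Butterworth coefficients come from the bilinear-transform design
#' ([signal::butter()]) at the requested half-amplitude cutoff; a bandpass is
#' realized as a high-pass/low-pass cascade. FIR designs are windowed-sinc
#' (Hamming) with the design cutoff found by bisection so that the composite
#' two-pass response is exactly half amplitude at the requested frequency.
#'
#' @param spec A [filter_spec()].
#' @param srate Sampling rate in Hz.
#' @return A `filter_design`: the spec, sampling rate and per-stage
#'   coefficients.
#' @export
design_filter <- function(spec, srate) {
  stopifnot(inherits(spec, "filter_spec"), srate > 0)
  nyq <- srate / 2
  if (any(spec$half_amp >= nyq))
    stop(sprintf("cutoff %g Hz at or above Nyquist (%g Hz)",
                 max(spec$half_amp), nyq), call. = FALSE)
  stages <- list()
  add_stage <- function(mode1, fc) {
    if (spec$kind == "butterworth") {
      n <- spec$rolloff / 12
      ba <- signal::butter(n, fc / nyq, type = if (mode1 == "lowpass") "low" else "high")
      stages[[length(stages) + 1L]] <<- list(mode = mode1, fc = fc, order = n,
                                             b = ba$b, a = ba$a)
    } else {
      h <- fir_design(mode1, fc, spec$fir_order, srate)
      stages[[length(stages) + 1L]] <<- list(mode = mode1, fc = fc,
                                             order = spec$fir_order, b = h, a = 1)
    }
  }
  if (spec$mode == "bandpass") {
    add_stage("highpass", spec$half_amp[1])
    add_stage("lowpass", spec$half_amp[2])
  } else {
    add_stage(spec$mode, spec$half_amp)
  }
  structure(list(spec = spec, srate = srate, stages = stages),
            class = "filter_design")
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# windowed-sinc FIR taps whose *composite* response is half amplitude at fc
fir_design <- function(mode1, fc, order, srate) {
  taps_lp <- function(fd) {
    k <- 0:order
    h <- 2 * fd / srate * sinc(2 * fd / srate * (k - order / 2))
    h <- h * (0.54 - 0.46 * cos(2 * pi * k / order))
    h / sum(h)                       # unity DC gain
  }
  taps <- function(fd) {
    if (mode1 == "lowpass") taps_lp(fd)
    else { h <- -taps_lp(fd); h[order / 2 + 1] <- h[order / 2 + 1] + 1; h }
  }
  amp_at <- function(h, f) Mod(sum(h * exp(-1i * 2 * pi * f / srate * (0:order))))
  target <- sqrt(0.5)                # composite |H|^2 = 0.5
  # bisection on the design cutoff; single-pass |H(fc)| is monotone in fd
  lo <- fc / 8; hi <- min(srate / 2 * 0.999, fc * 8)
  g <- function(fd) amp_at(taps(fd), fc) - target
  if (g(lo) * g(hi) > 0)
    stop("FIR design failed: cannot place half-amplitude cutoff at ", fc, " Hz",
         call. = FALSE)
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  taps((lo + hi) / 2)
}

#' Half-power cutoff corresponding to a half-amplitude specification
#'
#' A "cutoff at 30 Hz" is ambiguous: the frequency where 50% of *amplitude*
#' remains (6.02 dB down) is not the frequency where 50% of *power* remains
#' (3.01 dB down). Both should be distinguished when reporting. For a
#' Butterworth composite response the conversion has a closed form:
#' `f_hp = fc * (sqrt(2) - 1)^(1/(2n))` for a low-pass and
#' `f_hp = fc * (sqrt(2) - 1)^(-1/(2n))` for a high-pass of order n.
#'
#' @param spec A Butterworth [filter_spec()].
#' @return The half-power frequency in Hz (named vector of two for bandpass).
#' @export
half_power_from_half_amp <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind != "butterworth")
    stop("closed form applies to Butterworth only; evaluate the FIR response numerically",
         call. = FALSE)
  n <- spec$rolloff / 12
  r <- (sqrt(2) - 1)^(1 / (2 * n))
  switch(spec$mode,
    lowpass = spec$half_amp * r,
    highpass = spec$half_amp / r,
    bandpass = c(low = spec$half_amp[1] / r, high = spec$half_amp[2] * r))
}

#' Frequency response of the composite (two-pass) filter
#'
#' Returns the overall amplitude after forward-backward application — the
#' squared single-pass magnitude — evaluated at the requested frequencies.
#' For Butterworth stages the exact closed-form digital magnitude is used
#' (numerically robust at very low normalized cutoffs); FIR responses are
#' evaluated from the taps.
#'
#' @param design A [design_filter()] result.
#' @param freqs Frequencies in Hz, within (0, Nyquist).
#' @return Tibble with `freq_hz`, `amplitude` (linear, composite) and `db`
#'   (`20*log10(amplitude)`).
#' @export
freq_response <- function(design, freqs) {
  stopifnot(inherits(design, "filter_design"))
  fs <- design$srate
  amp <- rep(1, length(freqs))
  for (st in design$stages) {
    if (design$spec$kind == "butterworth") {
      x2n <- (tan(pi * freqs / fs) / tan(pi * st$fc / fs))^(2 * st$order)
      p <- if (st$mode == "lowpass") 1 / (1 + x2n) else x2n / (1 + x2n)
      amp <- amp * p                     # composite amplitude = single-pass power
    } else {
      k <- seq_along(st$b) - 1
      h1 <- vapply(freqs, function(f)
        Mod(sum(st$b * exp(-1i * 2 * pi * f / fs * k))), 0)
      amp <- amp * h1^2
    }
  }
  tibble::tibble(freq_hz = freqs, amplitude = amp, db = 20 * log10(amp))
}

#' Impulse response of the composite filter
#'
#' The response to a centered unit impulse after forward-backward
#' application: the time-domain picture of what the filter does to the data.
#' Zero-phase filtering makes it symmetric about its center.
#'
#' @param design A [design_filter()] result.
#' @param n Odd number of samples; the impulse sits at the center.
#' @return Numeric vector of length `n`.
#' @export
impulse_response <- function(design, n) {
  stopifnot(inherits(design, "filter_design"))
  if (n %% 2L != 1L) stop("n must be odd so the impulse can be centered", call. = FALSE)
  x <- numeric(n)
  x[(n + 1L) %/% 2L] <- 1
  filtfilt_stages(design, x)
}

# --- zero-phase application --------------------------------------------------

lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  if (nf == 1L) return(numeric(0))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  # companion matrix of a
  A <- rbind(-a[2:nf], cbind(diag(1, nf - 2L, nf - 2L), rep(0, nf - 2L)))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(nf - 1L) - t(A), B)
}

# one stage, forward-backward with odd-reflection padding and steady-state
# initial conditions (edge transients start from the local signal level)
filtfilt_one <- function(b, a, x, context = "segment") {
  n <- length(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen)
    stop(context, " too short to filter (", n, " samples, need > ", padlen, ")",
         call. = FALSE)
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

filtfilt_stages <- function(design, x, context = "segment") {
  for (st in design$stages) x <- filtfilt_one(st$b, st$a, x, context)
  x
}

#' Apply a zero-phase filter
#'
#' Applies the forward-backward filter per channel; epochs and averaged bins
#' are filtered whole. On continuous data with `per_block = TRUE` the
#' recording is split at boundary markers and each trial block filtered
#' independently, so a DC-offset change between blocks cannot be smeared into
#' a long artifact spanning the boundary; with `remove_dc = TRUE` each
#' filtered segment's mean is subtracted first (the implicit transition from
#' 0 microvolts to a large offset at the segment edge would otherwise create
#' edge artifacts).
#'
#' @param obj An `erp_continuous`, `erp_epochs` or `erp_set`.
#' @param spec A [filter_spec()].
#' @return The filtered object of the same kind.
#' @export
apply_filter <- function(obj, spec) {
  stopifnot(inherits(obj, c("erp_continuous", "erp_epochs", "erp_set")),
            inherits(spec, "filter_spec"))
  design <- design_filter(spec, obj$srate)
  filt_seg <- function(x, context) {
    if (spec$remove_dc) x <- x - mean(x)
    filtfilt_stages(design, x, context)
  }
  if (inherits(obj, "erp_continuous")) {
    ns <- ncol(obj$data)
    cuts <- if (spec$per_block) sort(unique(c(0L, obj$boundaries, ns))) else c(0L, ns)
    cuts <- cuts[cuts >= 0L & cuts <= ns]
    for (i in seq_len(length(cuts) - 1L)) {
      idx <- (cuts[i] + 1L):cuts[i + 1L]
      ctx <- sprintf("block %d (%d samples)", i, length(idx))
      for (ch in seq_len(nrow(obj$data)))
        obj$data[ch, idx] <- filt_seg(obj$data[ch, idx], ctx)
    }
  } else if (inherits(obj, "erp_epochs")) {
    for (e in seq_len(dim(obj$data)[1]))
      for (ch in seq_len(dim(obj$data)[2]))
        obj$data[e, ch, ] <- filt_seg(obj$data[e, ch, ], sprintf("epoch %d", e))
  } else {
    for (b in seq_len(dim(obj$data)[1]))
      for (ch in seq_len(dim(obj$data)[2]))
        obj$data[b, ch, ] <- filt_seg(obj$data[b, ch, ], sprintf("bin %d", b))
  }
  obj <- assert_finite(obj)
  append_history(obj, sprintf(
    'apply_filter(x, filter_spec(mode = "%s", half_amp = c(%s), kind = "%s", rolloff = %g, fir_order = %d, remove_dc = %s, per_block = %s))',
    spec$mode, paste(spec$half_amp, collapse = ","), spec$kind, spec$rolloff,
    spec$fir_order, spec$remove_dc, spec$per_block))
}
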