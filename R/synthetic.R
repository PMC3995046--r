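#' Configuration for the synthetic oddball session
#'
#' Builds the parameter set for [simulate_oddball()], which emulates a
#' classic two-stimulus oddball experiment: frequent standards (codes 11/12)
#' and rare oddballs (codes 21/22, probability `p_oddball`), each followed by
#' a button-press response (code 101) after a truncated-normal reaction time,
#' recorded in `n_blocks` trial blocks separated by gaps (boundary markers)
#' with block-specific DC offsets. Stimulus-locked components are Gaussian
#' bumps with per-channel topographies; by default every stimulus evokes a
#' small P1/N1 complex and a P3 whose Pz peak is 10 microvolts for rare and
#' 2 microvolts for frequent stimuli (an 8 microvolt rare-minus-frequent
#' effect) at 450 ms with a 60 ms standard deviation. Ongoing activity is
#' AR(1) noise (marginal SD `noise_sd`) plus a 10 Hz alpha sinusoid.
#' Artifacts: raised-cosine eyeblinks on VEOG with scaled frontal leakage,
#' step-like (saccade) excursions on HEOG, and short nearly-constant
#' (blocking) segments on all channels.
#'
#' @param srate Sampling rate, Hz.
#' @param n_trials Number of stimuli across the session.
#' @param p_oddball Probability a trial is rare.
#' @param soa_mean_ms,soa_jitter_ms Stimulus-onset asynchrony: uniform jitter
#'   around the mean.
#' @param rt_mean_ms,rt_sd_ms,rt_bounds_ms Truncated-normal reaction time
#'   model for the response event.
#' @param noise_ar,noise_sd AR(1) coefficient and marginal SD (microvolts).
#' @param alpha_amp Amplitude of the 10 Hz alpha sinusoid (microvolts).
#' @param blink_rate_per_min,blink_amp,blink_dur_ms Eyeblink model (VEOG
#'   amplitude; frontal channels get a scaled copy).
#' @param step_rate_per_min,step_amp Step-artifact (saccade) model on HEOG.
#' @param flat_rate_per_min,flat_dur_ms Blocking-segment model.
#' @param n_blocks,dc_offsets_uv Trial blocks and their DC offsets (recycled
#'   to `n_blocks`).
#' @param components List of component definitions; each is a list with
#'   `codes` (stimulus codes that evoke it), `latency_ms`, `sigma_ms`, and
#'   `amp` (per-channel peak amplitudes, microvolts).
#' @param seed Integer seed; the simulation is fully determined by it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(srate = 500, n_trials = 400, p_oddball = 0.2,
                       soa_mean_ms = 1500, soa_jitter_ms = 200,
                       rt_mean_ms = 450, rt_sd_ms = 120,
                       rt_bounds_ms = c(200, 1000),
                       noise_ar = 0.95, noise_sd = 5, alpha_amp = 2,
                       blink_rate_per_min = 4, blink_amp = 200,
                       blink_dur_ms = 250,
                       step_rate_per_min = 1, step_amp = 60,
                       flat_rate_per_min = 0.5, flat_dur_ms = 400,
                       n_blocks = 2, dc_offsets_uv = c(0, 50),
                       components = NULL, seed = 1L) {
  chan_labels <- c("Fz", "Cz", "Pz", "Oz", "VEOG", "HEOG")
  if (is.null(components)) {
    stim <- c(11L, 12L, 21L, 22L)
    components <- list(
      list(name = "P1", codes = stim, latency_ms = 100, sigma_ms = 20,
           amp = c(Fz = 0.5, Cz = 1, Pz = 1.5, Oz = 2, VEOG = 0, HEOG = 0)),
      list(name = "N1", codes = stim, latency_ms = 170, sigma_ms = 25,
           amp = c(Fz = -1, Cz = -2, Pz = -2.5, Oz = -3, VEOG = 0, HEOG = 0)),
      list(name = "P3_rare", codes = c(21L, 22L), latency_ms = 450, sigma_ms = 60,
           amp = c(Fz = 5, Cz = 8, Pz = 10, Oz = 6, VEOG = 0, HEOG = 0)),
      list(name = "P3_frequent", codes = c(11L, 12L), latency_ms = 450, sigma_ms = 60,
           amp = c(Fz = 1, Cz = 1.6, Pz = 2, Oz = 1.2, VEOG = 0, HEOG = 0))
    )
  }
  stopifnot(p_oddball >= 0, p_oddball <= 1, rt_bounds_ms[1] < rt_bounds_ms[2],
            noise_sd >= 0, blink_rate_per_min >= 0, step_rate_per_min >= 0,
            flat_rate_per_min >= 0, n_blocks >= 1)
  structure(list(
    srate = srate, chan_labels = chan_labels, n_trials = n_trials,
    p_oddball = p_oddball, soa_mean_ms = soa_mean_ms, soa_jitter_ms = soa_jitter_ms,
    codes_frequent = c(11L, 12L), codes_rare = c(21L, 22L), code_response = 101L,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms, rt_bounds_ms = rt_bounds_ms,
    noise_ar = noise_ar, noise_sd = noise_sd, alpha_amp = alpha_amp,
    blink_rate_per_min = blink_rate_per_min, blink_amp = blink_amp,
    blink_dur_ms = blink_dur_ms,
    blink_leak = c(Fz = 0.4, Cz = 0.2, Pz = 0.1, Oz = 0.05, VEOG = 1, HEOG = 0.02),
    step_rate_per_min = step_rate_per_min, step_amp = step_amp,
    flat_rate_per_min = flat_rate_per_min, flat_dur_ms = flat_dur_ms,
    n_blocks = n_blocks,
    dc_offsets_uv = rep_len(dc_offsets_uv, n_blocks),
    components = components, seed = as.integer(seed)
  ), class = "sim_config")
}

# Gaussian component bump on a sample grid, truncated at 4 sigma.
# Shift-invariant: for grid-aligned latencies the same samples and values come
# out whether the grid origin is the recording start or the epoch start, which
# is what makes expected_erp() agree exactly with the generator.
gauss_bump <- function(ns, fs, lat_s, sig_s) {
  # support computed in integer sample units so it is exactly shift invariant
  center <- round(lat_s * fs)                       # 0-based center sample
  w <- ceiling(4 * sig_s * fs + 1e-9)
  j0 <- max(1L, as.integer(center - w + 1L))
  j1 <- min(ns, as.integer(center + w + 1L))
  if (j1 < j0) return(list(idx = integer(), val = numeric()))
  tt <- ((j0:j1) - 1L) / fs
  list(idx = j0:j1, val = exp(-(tt - lat_s)^2 / (2 * sig_s^2)))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Simulate a continuous oddball EEG recording with known ground truth
#'
#' Generates the continuous recording described by the configuration —
#' block DC offsets + AR(1) noise + alpha + stimulus-locked Gaussian
#' components + artifacts — with every random draw determined by
#' `config$seed`. The ground truth records, per trial, the stimulus code,
#' onset, reaction time, block, and whether a blink peak falls within the
#' canonical epoch window `[-200, 800)` ms around the stimulus, plus the
#' artifact and block tables, so every downstream stage can be validated
#' against what was actually put in.
#'
#' @param config A [sim_config()].
#' @return List with `eeg` (`erp_continuous`) and `truth` (list of tibbles:
#'   `trials`, `blinks`, `steps`, `flats`, `blocks`).
#' @export
simulate_oddball <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_oddball_impl(config))
}

simulate_oddball_impl <- function(cfg) {
  fs <- cfg$srate
  nch <- length(cfg$chan_labels)
  pad_s <- 2

  # --- trial timeline over blocks -------------------------------------------
  per_block <- diff(round(seq(0, cfg$n_trials, length.out = cfg$n_blocks + 1)))
  soa <- (cfg$soa_mean_ms + stats::runif(cfg$n_trials, -cfg$soa_jitter_ms,
                                         cfg$soa_jitter_ms)) / 1000
  is_rare <- stats::runif(cfg$n_trials) < cfg$p_oddball
  code <- integer(cfg$n_trials)
  code[is_rare] <- sample(cfg$codes_rare, sum(is_rare), replace = TRUE)
  code[!is_rare] <- sample(cfg$codes_frequent, sum(!is_rare), replace = TRUE)
  rt <- rtruncnorm1(cfg$n_trials, cfg$rt_mean_ms, cfg$rt_sd_ms,
                    cfg$rt_bounds_ms[1], cfg$rt_bounds_ms[2])
  rt <- round(rt * fs / 1000) * 1000 / fs       # responses land on the grid too

  onset <- numeric(cfg$n_trials)
  block <- integer(cfg$n_trials)
  boundaries <- integer(0)
  t0 <- 0           # running block start, seconds
  trial <- 1L
  block_tbl <- list()
  for (b in seq_len(cfg$n_blocks)) {
    if (b > 1L) boundaries <- c(boundaries, round(t0 * fs))
    tcur <- t0 + pad_s
    bstart <- t0
    for (j in seq_len(per_block[b])) {
      onset[trial] <- round(tcur * fs) / fs     # events land on the sample grid
      block[trial] <- b
      tcur <- tcur + soa[trial]
      trial <- trial + 1L
    }
    t0 <- tcur + pad_s
    block_tbl[[b]] <- tibble::tibble(block = b, start_s = bstart, end_s = t0,
                                     dc_offset_uv = cfg$dc_offsets_uv[b])
  }
  total_s <- t0
  ns <- ceiling(total_s * fs)

  # --- signal ----------------------------------------------------------------
  data <- matrix(0, nch, ns)
  for (b in seq_len(cfg$n_blocks)) {
    i0 <- round(block_tbl[[b]]$start_s * fs) + 1L
    i1 <- if (b < cfg$n_blocks) round(block_tbl[[b + 1L]]$start_s * fs) else ns
    data[, i0:i1] <- data[, i0:i1] + cfg$dc_offsets_uv[b]
  }
  if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar^2)
    for (ch in seq_len(nch)) {
      e <- stats::rnorm(ns, 0, innov_sd)
      data[ch, ] <- data[ch, ] +
        as.numeric(stats::filter(e, cfg$noise_ar, method = "recursive"))
    }
  }
  if (cfg$alpha_amp > 0) {
    tt <- (seq_len(ns) - 1L) / fs
    for (ch in seq_len(nch))
      data[ch, ] <- data[ch, ] +
        cfg$alpha_amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
  }
  # stimulus-locked components: Gaussian bumps, truncated at 4 sigma
  for (tr in seq_len(cfg$n_trials)) {
    for (comp in cfg$components) {
      if (!(code[tr] %in% comp$codes)) next
      bump <- gauss_bump(ns, fs, onset[tr] + comp$latency_ms / 1000,
                         comp$sigma_ms / 1000)
      amp <- comp$amp[cfg$chan_labels]
      amp[is.na(amp)] <- 0
      for (ch in seq_len(nch))
        if (amp[ch] != 0)
          data[ch, bump$idx] <- data[ch, bump$idx] + amp[ch] * bump$val
    }
  }

  # --- artifacts -------------------------------------------------------------
  minutes <- total_s / 60
  place_uniform <- function(n) sort(stats::runif(n, 1, total_s - 2))
  n_blinks <- stats::rpois(1, cfg$blink_rate_per_min * minutes)
  blink_on <- place_uniform(n_blinks)
  for (bo in blink_on) {
    dur <- cfg$blink_dur_ms / 1000
    j0 <- round(bo * fs) + 1L
    j1 <- min(ns, round((bo + dur) * fs))
    tt <- ((j0:j1) - j0) / fs
    shape <- 0.5 * (1 - cos(2 * pi * tt / dur))      # raised cosine, peak at mid
    for (ch in seq_len(nch)) {
      leak <- cfg$blink_leak[cfg$chan_labels[ch]]
      if (!is.na(leak) && leak != 0)
        data[ch, j0:j1] <- data[ch, j0:j1] + cfg$blink_amp * leak * shape
    }
  }
  n_steps <- stats::rpois(1, cfg$step_rate_per_min * minutes)
  step_on <- place_uniform(n_steps)
  heog <- match("HEOG", cfg$chan_labels)
  for (so in step_on) {
    j0 <- round(so * fs) + 1L
    j1 <- min(ns, round((so + 0.3) * fs))            # gaze held ~300 ms
    data[heog, j0:j1] <- data[heog, j0:j1] + sample(c(-1, 1), 1) * cfg$step_amp
  }
  n_flats <- stats::rpois(1, cfg$flat_rate_per_min * minutes)
  flat_on <- place_uniform(n_flats)
  for (fo in flat_on) {
    j0 <- round(fo * fs) + 1L
    j1 <- min(ns, round((fo + cfg$flat_dur_ms / 1000) * fs))
    # blocking: hold at the saturation level, nearly but not perfectly constant
    data[, j0:j1] <- data[, j0] + matrix(stats::rnorm(nch * (j1 - j0 + 1L), 0, 0.05),
                                         nch)
  }

  # --- events & ground truth -------------------------------------------------
  ev_tbl <- tibble::tibble(
    code = c(code, rep(cfg$code_response, cfg$n_trials)),
    label = c(ifelse(is_rare, "rare", "frequent"), rep("resp", cfg$n_trials)),
    onset = c(onset, onset + rt / 1000)
  )
  ev_tbl <- ev_tbl[order(ev_tbl$onset), ]
  eeg <- continuous_eeg(data, srate = fs, chan_labels = cfg$chan_labels,
                        events = eventlist(ev_tbl, srate = fs),
                        boundaries = boundaries)
  eeg <- append_history(eeg, sprintf("simulate_oddball(sim_config(seed = %d))", cfg$seed))

  blink_peak <- blink_on + cfg$blink_dur_ms / 2000
  contaminated <- vapply(onset, function(o)
    any(blink_peak >= o - 0.2 & blink_peak < o + 0.8), TRUE)
  truth <- list(
    trials = tibble::tibble(
      trial = seq_len(cfg$n_trials), block = block, code = code,
      is_rare = is_rare, onset_s = onset, rt_ms = rt,
      blink_contaminated = contaminated
    ),
    blinks = tibble::tibble(onset_s = blink_on, peak_s = blink_peak),
    steps = tibble::tibble(onset_s = step_on),
    flats = tibble::tibble(onset_s = flat_on, duration_ms = cfg$flat_dur_ms),
    blocks = dplyr::bind_rows(block_tbl)
  )
  list(eeg = eeg, truth = truth)
}

#' Analytic expected ERP implied by the component model
#'
#' The noise-free, artifact-free average waveform for stimuli in `code_set`:
#' the sum of the configured Gaussian components evoked by those codes,
#' evaluated on the epoch time grid. Used as the recovery target when
#' validating the full pipeline against the simulator.
#'
#' @param config A [sim_config()].
#' @param code_set Integer stimulus codes defining the (single) bin.
#' @param tmin,tmax Epoch window in ms.
#' @return An `erp_set` with one bin.
#' @export
expected_erp <- function(config, code_set, tmin = -200, tmax = 800) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(code_set)) stop("code_set must not be empty", call. = FALSE)
  fs <- config$srate
  n <- round((tmax - tmin) * fs / 1000)
  tm <- tmin + (seq_len(n) - 1L) * 1000 / fs
  nch <- length(config$chan_labels)
  data <- array(0, dim = c(1L, nch, n))
  for (comp in config$components) {
    if (!any(code_set %in% comp$codes)) next
    if (!all(code_set %in% comp$codes))
      warning("code_set mixes codes that do and do not evoke component ",
              comp$name %||% "?", call. = FALSE)
    # same truncated-bump construction as the generator, on the epoch grid
    bump <- gauss_bump(n, fs, (comp$latency_ms - tmin) / 1000,
                       comp$sigma_ms / 1000)
    amp <- comp$amp[config$chan_labels]
    amp[is.na(amp)] <- 0
    for (ch in seq_len(nch))
      data[1, ch, bump$idx] <- data[1, ch, bump$idx] + amp[ch] * bump$val
  }
  erp_set(data, srate = fs, tmin = tmin, tmax = tmax,
          bin_labels = paste(code_set, collapse = "/"),
          chan_labels = config$chan_labels, subject = "expected")
}

#' Read a simulator configuration from a key = value text file
#'
#' Recognized keys are the scalar/vector arguments of [sim_config()] (vector
#' values comma-separated); unknown keys are an error. Lines starting with
#' `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  args <- list()
  numeric_keys <- c("srate", "n_trials", "p_oddball", "soa_mean_ms",
                    "soa_jitter_ms", "rt_mean_ms", "rt_sd_ms", "rt_bounds_ms",
                    "noise_ar", "noise_sd", "alpha_amp", "blink_rate_per_min",
                    "blink_amp", "blink_dur_ms", "step_rate_per_min",
                    "step_amp", "flat_rate_per_min", "flat_dur_ms",
                    "n_blocks", "dc_offsets_uv", "seed")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("line ", i, ": expected 'key = value'", call. = FALSE)
    if (!m[2] %in% numeric_keys) stop("line ", i, ": unknown key '", m[2], "'",
                                      call. = FALSE)
    args[[m[2]]] <- as.numeric(strsplit(m[3], ",")[[1]])
  }
  do.call(sim_config, args)
}
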