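# Shared fixtures: all built in code at test time.

# continuous recording with given per-channel constant values
make_constant_eeg <- function(values, n_samples = 1000, srate = 1000,
                              labels = NULL, events = NULL, boundaries = integer()) {
  data <- matrix(rep(values, each = n_samples), nrow = length(values),
                 byrow = TRUE)
  continuous_eeg(data, srate = srate, chan_labels = labels, events = events,
                 boundaries = boundaries)
}

# epoched object with one constant value per epoch (single bin, single channel
# unless given a matrix: epochs x channels)
make_constant_epochs <- function(values, bins = NULL, srate = 1000,
                                 tmin = -100, tmax = 500) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  n_ep <- nrow(values); n_ch <- ncol(values)
  n_s <- round((tmax - tmin) * srate / 1000)
  data <- array(0, dim = c(n_ep, n_ch, n_s))
  for (e in seq_len(n_ep)) for (ch in seq_len(n_ch)) data[e, ch, ] <- values[e, ch]
  if (is.null(bins)) bins <- rep(list(1L), n_ep)
  ev <- eventlist(tibble::tibble(code = rep(1L, n_ep),
                                 onset = seq_len(n_ep)), srate = srate)
  epoched_eeg(data, srate = srate, tmin = tmin, tmax = tmax,
              chan_labels = paste0("ch", seq_len(n_ch)),
              epochs = tibble::tibble(epoch = seq_len(n_ep),
                                      item = seq_len(n_ep), bins = bins),
              events = ev)
}

# ERP set with one constant value per (bin, channel)
make_constant_erp <- function(values, srate = 1000, tmin = -100, tmax = 500,
                              n_accepted = NULL, subject = "") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  nb <- nrow(values); nc <- ncol(values)
  ns <- round((tmax - tmin) * srate / 1000)
  data <- array(0, dim = c(nb, nc, ns))
  for (b in seq_len(nb)) for (ch in seq_len(nc)) data[b, ch, ] <- values[b, ch]
  counts <- tibble::tibble(bin = seq_len(nb),
                           n_accepted = if (is.null(n_accepted)) 0L
                                        else as.integer(rep_len(n_accepted, nb)),
                           n_rejected = 0L)
  erp_set(data, srate = srate, tmin = tmin, tmax = tmax,
          chan_labels = paste0("ch", seq_len(nc)), counts = counts,
          subject = subject)
}

# ERP set holding an arbitrary single waveform (1 bin, 1 channel)
make_wave_erp <- function(wave, srate = 1000, tmin = 0) {
  data <- array(wave, dim = c(1, 1, length(wave)))
  erp_set(data, srate = srate, tmin = tmin,
          tmax = tmin + length(wave) * 1000 / srate, chan_labels = "ch1")
}

# --- independent brute-force bin matcher -------------------------------------
# Enumerates every contiguous window of the enabled subsequence and tests all
# items directly; used as the equivalence oracle for assign_bins().
brute_force_bins <- function(ev, descriptors) {
  e <- ev$events
  out <- rep(list(integer()), nrow(e))
  en <- which(e$enabled)
  for (d in descriptors) {
    items <- c(d$pre_items, list(d$home_item), d$post_items)
    L <- length(items)
    hp <- length(d$pre_items) + 1L       # home position in the window
    if (length(en) < L) next
    for (s in seq_len(length(en) - L + 1L)) {
      win <- en[s:(s + L - 1L)]
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(e$code[win[j]] %in% items[[j]]$codes)) { ok <- FALSE; break }
        tw <- items[[j]]$time_window
        if (!is.null(tw)) {
          dt <- (e$onset[win[j]] - e$onset[win[j - 1L]]) * 1000
          # endpoints inclusive, to float tolerance
          if (dt < tw[1] - 1e-9 || dt > tw[2] + 1e-9) { ok <- FALSE; break }
        }
      }
      if (ok) {
        h <- win[hp]
        if (!(d$bin_number %in% out[[h]]))
          out[[h]] <- c(out[[h]], d$bin_number)
      }
    }
  }
  out
}

# random event stream and random descriptor for the equivalence property
random_stream <- function(n_events, n_codes = 8, srate = 500) {
  onset <- sort(runif(n_events, 0, n_events * 0.3))
  eventlist(tibble::tibble(
    code = sample.int(n_codes, n_events, replace = TRUE),
    onset = onset,
    enabled = runif(n_events) > 0.1
  ), srate = srate)
}

random_descriptor <- function(bin_number, n_codes = 8) {
  item <- function(allow_tw) {
    codes <- sort(sample.int(n_codes, sample(1:2, 1)))
    tw <- NULL
    if (allow_tw && runif(1) < 0.5) {
      a <- round(runif(1, 0, 400)); b <- a + round(runif(1, 50, 600))
      tw <- c(a, b)
    }
    list(codes = codes, time_window = tw, rt_name = NULL, pos = 1L)
  }
  k <- sample(0:2, 1); l <- sample(0:2, 1)
  pre <- lapply(seq_len(k), function(j) item(j > 1))
  post <- lapply(seq_len(l), function(j) item(TRUE))
  structure(list(bin_number = bin_number, label = "rnd",
                 pre_items = pre, home_item = item(FALSE), post_items = post),
            class = "bin_descriptor")
}

# --- independent expression-tree interpreter ---------------------------------
# Direct recursive evaluation used as the oracle for the equation engine.
eval_ast_reference <- function(node, chan_data) {
  ev <- function(n) {
    switch(n$t,
      num = n$v,
      ref = chan_data[[n$index]],
      neg = -ev(n$a),
      call = if (n$fn == "sqrt") sqrt(ev(n$a)) else abs(ev(n$a)),
      avgchan = {
        idx <- unlist(lapply(n$ranges, function(r) seq(r[1], r[2])))
        Reduce(`+`, chan_data[idx]) / length(idx)
      },
      bin2 = {
        a <- ev(n$a); b <- ev(n$b)
        switch(n$op, `+` = a + b, `-` = a - b, `*` = a * b, `/` = a / b, `^` = a^b)
      })
  }
  ev(node)
}

# random expression tree over chan refs, depth-limited, division-free
random_expr_text <- function(n_chan, depth = 4) {
  leaf <- function() {
    if (runif(1) < 0.6) paste0("chan", sample.int(n_chan, 1))
    else format(round(runif(1, 0.5, 5), 3))
  }
  gen <- function(d) {
    if (d <= 0 || runif(1) < 0.3) return(leaf())
    op <- sample(c("+", "-", "*"), 1)
    paste0("(", gen(d - 1), op, gen(d - 1), ")")
  }
  gen(depth)
}
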