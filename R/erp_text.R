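#' Write averaged ERP waveforms to the text interchange format
#'
#' All bins of an ERP set go into a single file. For each bin the file holds a
#' header line `bin <k> <label>`, a column-header line
#' `time_ms <channel labels...>`, then one tab-separated row per sample: the
#' time in ms followed by one microvolt value per channel, six decimals. The
#' format is meant for moving averaged waveforms between analysis packages.
#'
#' @param erp An `erp_set`.
#' @param path Output file path.
#' @return `erp`, invisibly.
#' @export
write_erp_text <- function(erp, path) {
  stopifnot(inherits(erp, "erp_set"))
  if (any(grepl("\t", erp$bin_labels)))
    stop("bin labels must be tab-free", call. = FALSE)
  if (any(grepl("\t", erp$chan_labels)))
    stop("channel labels must be tab-free", call. = FALSE)
  tm <- time_axis(erp)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'", call. = FALSE))
  on.exit(close(con))
  for (b in seq_len(dim(erp$data)[1])) {
    writeLines(sprintf("bin %d %s", b, erp$bin_labels[b]), con)
    writeLines(paste(c("time_ms", erp$chan_labels), collapse = "\t"), con)
    block <- rbind(tm, matrix(erp$data[b, , ], nrow = dim(erp$data)[2]))
    writeLines(apply(block, 2, function(col)
      paste(sprintf("%.6f", col), collapse = "\t")), con)
  }
  invisible(erp)
}

#' Read averaged ERP waveforms from the text interchange format
#'
#' The inverse of [write_erp_text()]. The sampling rate is inferred from the
#' spacing of the time column (which must be uniform); trial counts are
#' unknown for imported data and set to zero.
#'
#' @param path Path to an ERP text file.
#' @return An `erp_set`.
#' @export
read_erp_text <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^bin ", lines)
  if (!length(starts)) stop("no 'bin' headers found in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  bins <- vector("list", length(starts))
  labels <- character(length(starts))
  chans <- NULL
  tm <- NULL
  for (i in seq_along(starts)) {
    hdr <- strsplit(lines[starts[i]], " ")[[1]]
    labels[i] <- if (length(hdr) >= 3L) paste(hdr[-(1:2)], collapse = " ") else ""
    cols <- strsplit(lines[starts[i] + 1L], "\t")[[1]]
    if (cols[1] != "time_ms") stop("malformed column header in bin ", i, call. = FALSE)
    this_chans <- cols[-1]
    if (is.null(chans)) chans <- this_chans
    else if (!identical(chans, this_chans))
      stop("bins have differing channel sets", call. = FALSE)
    body <- lines[(starts[i] + 2L):ends[i]]
    body <- body[nzchar(trimws(body))]
    m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    if (ncol(m) != length(chans) + 1L)
      stop("wrong column count in bin ", i, call. = FALSE)
    this_tm <- m[, 1]
    if (is.null(tm)) {
      tm <- this_tm
      dt <- diff(tm)
      if (length(dt)) {
        rel <- abs(dt - dt[1]) / max(abs(dt[1]), .Machine$double.eps)
        if (any(rel > 1e-9))
          stop("non-uniform time spacing in ", path, call. = FALSE)
      }
    } else if (length(this_tm) != length(tm)) {
      stop("bins have differing sample counts", call. = FALSE)
    }
    bins[[i]] <- t(m[, -1, drop = FALSE])  # channels x samples
  }
  srate <- 1000 / (tm[2] - tm[1])
  data <- array(0, dim = c(length(bins), length(chans), length(tm)))
  for (i in seq_along(bins)) data[i, , ] <- bins[[i]]
  tmin <- tm[1]
  tmax <- tm[1] + length(tm) * 1000 / srate
  erp_set(data, srate = srate, tmin = tmin, tmax = tmax,
          bin_labels = labels, chan_labels = chans)
}
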