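#' Event lists
#'
#' An event list is the ordered record of everything that happened during an
#' EEG recording: stimulus and response event codes, their onsets, an
#' enable/disable flag, eight artifact flags, eight user flags, and the
#' averaging bins each event has been assigned to. It is the central bookkeeping
#' structure connecting event-code processing, epoching and artifact detection.
#'
#' @param events A data frame with columns `item`, `code`, `label`, `onset`,
#'   `duration`, `enabled`, `bins` (list column of integer vectors),
#'   `artifact_flags`, `user_flags` (8-character "0"/"1" strings). Missing
#'   columns are filled with defaults.
#' @param srate Sampling rate of the parent recording in Hz.
#' @return An object of class `erp_eventlist`.
#' @export
eventlist <- function(events = NULL, srate) {
  stopifnot(is.numeric(srate), length(srate) == 1L, srate > 0)
  if (is.null(events) || nrow(events) == 0L) {
    events <- tibble::tibble(
      item = integer(), code = integer(), label = character(),
      onset = numeric(), duration = numeric(), enabled = logical(),
      bins = list(), artifact_flags = character(), user_flags = character()
    )
  } else {
    events <- tibble::as_tibble(events)
    n <- nrow(events)
    has <- function(col) col %in% names(events)
    if (!has("item")) events$item <- seq_len(n)
    if (!has("label")) events$label <- as.character(events$code)
    if (!has("duration")) events$duration <- rep(0, n)
    if (!has("enabled")) events$enabled <- rep(TRUE, n)
    if (!has("bins")) events$bins <- rep(list(integer()), n)
    if (!has("artifact_flags")) events$artifact_flags <- rep(strrep("0", 8L), n)
    if (!has("user_flags")) events$user_flags <- rep(strrep("0", 8L), n)
    events <- events[order(events$onset), ]
    events$item <- seq_len(n)
    events <- events[, c("item", "code", "label", "onset", "duration",
                         "enabled", "bins", "artifact_flags", "user_flags")]
  }
  ev <- structure(list(events = events, srate = srate), class = "erp_eventlist")
  validate_eventlist(ev)
  ev
}

validate_eventlist <- function(ev) {
  e <- ev$events
  if (nrow(e)) {
    if (!identical(as.integer(e$item), seq_len(nrow(e))))
      stop("event item indices must be consecutive starting at 1", call. = FALSE)
    if (is.unsorted(e$onset))
      stop("event onsets must be non-decreasing", call. = FALSE)
    if (any(nchar(e$artifact_flags) != 8L) || any(nchar(e$user_flags) != 8L))
      stop("flag strings must be 8 characters", call. = FALSE)
    if (any(vapply(e$bins, anyDuplicated, 0L) > 0L))
      stop("bin assignments must not contain duplicates", call. = FALSE)
  }
  invisible(ev)
}

#' @export
print.erp_eventlist <- function(x, ...) {
  cat(sprintf("<erp_eventlist> %d events, srate %g Hz\n", nrow(x$events), x$srate))
  if (nrow(x$events)) print(utils::head(x$events, 10L))
  invisible(x)
}

#' @export
as_tibble.erp_eventlist <- function(x, ...) x$events

n_events <- function(ev) nrow(ev$events)

# flag-string helpers: flags stored as 8-char "0"/"1" strings, flag 1 leftmost
flag_get <- function(s, k) substr(s, k, k) == "1"
flag_set <- function(s, k, value = TRUE) {
  substr(s, k, k) <- if (value) "1" else "0"
  s
}

fmt_bins <- function(bins) {
  if (length(bins) == 0L) "-" else paste(bins, collapse = ",")
}

#' Write an event list as editable text
#'
#' The file has `#` comment header lines (format version and sampling rate)
#' followed by one whitespace-delimited row per event:
#' `item code label onset_s duration_s enabled bins artifact_flags user_flags`.
#' Onset and duration are printed with six decimals; `bins` is a comma-separated
#' list or `-` when empty; the flag fields are 8-character 0/1 strings. The file
#' can be edited (rows inserted, codes changed, events disabled) and read back
#' with [read_eventlist_text()].
#'
#' @param ev An `erp_eventlist`.
#' @param path Output file path.
#' @return `ev`, invisibly.
#' @export
write_eventlist_text <- function(ev, path) {
  stopifnot(inherits(ev, "erp_eventlist"))
  e <- ev$events
  if (any(grepl("[[:space:]]", e$label)))
    stop("event labels must not contain whitespace", call. = FALSE)
  lines <- c(
    "# erpkit EVENTLIST text v1",
    sprintf("# srate_hz %.6f", ev$srate),
    "# columns: item code label onset_s duration_s enabled bins aflags uflags"
  )
  if (nrow(e)) {
    rows <- sprintf("%d %d %s %.6f %.6f %d %s %s %s",
                    e$item, e$code, e$label, e$onset, e$duration,
                    as.integer(e$enabled),
                    vapply(e$bins, fmt_bins, ""),
                    e$artifact_flags, e$user_flags)
    lines <- c(lines, rows)
  }
  tryCatch(writeLines(lines, path),
           error = function(err) stop("cannot write '", path, "': ",
                                      conditionMessage(err), call. = FALSE))
  invisible(ev)
}

#' Read an event list from its text format
#'
#' Parses a file written by [write_eventlist_text()] (possibly edited by hand).
#' Rows are re-sorted by onset and item indices renumbered, so inserting a row
#' anywhere in the file yields a valid list. Malformed rows raise an error
#' naming the offending line.
#'
#' @param path Path to an EVENTLIST text file.
#' @return An `erp_eventlist`.
#' @export
read_eventlist_text <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  srate <- NA_real_
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*srate_hz\\s+([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2L) srate <- as.numeric(m[2])
  }
  if (!is.finite(srate)) stop("missing '# srate_hz' header", call. = FALSE)
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 9L)
      stop(sprintf("line %d: expected 9 fields, found %d", i, length(f)), call. = FALSE)
    if (nchar(f[8]) != 8L || nchar(f[9]) != 8L)
      stop(sprintf("line %d: flags must be 8 characters", i), call. = FALSE)
    if (!grepl("^[01]{8}$", f[8]) || !grepl("^[01]{8}$", f[9]))
      stop(sprintf("line %d: flags must be 0/1 strings", i), call. = FALSE)
    onset <- suppressWarnings(as.numeric(f[4]))
    code <- suppressWarnings(as.integer(f[2]))
    if (is.na(onset) || is.na(code))
      stop(sprintf("line %d: malformed numeric field", i), call. = FALSE)
    bins <- if (f[7] == "-") integer() else as.integer(strsplit(f[7], ",")[[1]])
    if (anyNA(bins)) stop(sprintf("line %d: malformed bin list", i), call. = FALSE)
    tibble::tibble(
      item = as.integer(f[1]), code = code, label = f[3], onset = onset,
      duration = as.numeric(f[5]), enabled = f[6] == "1",
      bins = list(bins), artifact_flags = f[8], user_flags = f[9]
    )
  })
  events <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  if (!is.null(events) && is.unsorted(events$onset)) {
    bad <- which(diff(events$onset) < 0)[1] + 1L
    stop(sprintf("line %d: onsets must be non-decreasing", body_idx[bad]), call. = FALSE)
  }
  eventlist(events, srate = srate)
}
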