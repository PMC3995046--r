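#' Bin descriptors: sorting event codes into averaging bins
#'
#' In most systems an averaging bin is one event code; real experiments need
#' more: a counterbalanced oddball lumps "X when X is rare" and "Y when Y is
#' rare" into one bin, and one often wants only the targets that were followed
#' by a correct response within a latency window. A bin descriptor expresses
#' such conditions as an abstract event-sequence pattern, e.g.
#'
#' ```
#' {11;12}.{21;22}{t<200-1000>101}
#' ```
#'
#' "an event with code 21 or 22 (the *home* item, marked by the dot), preceded
#' immediately by 11 or 12 and followed immediately by 101 arriving 200-1000 ms
#' after the home event". A post item may also capture a reaction time:
#' `{101:rt<"RT_Correct_Response">}` records the latency of the matched 101
#' relative to the home event under that name.
#'
#' @section File format:
#' Three lines per bin: `bin <k>`, a label line, and the pattern line. Items
#' are `{...}` groups; alternative codes are separated by `;`; a latency
#' condition `t<min-max>` (ASCII hyphen or en-dash) is measured relative to
#' the immediately preceding item's matched event; window endpoints are
#' inclusive. Items match strictly consecutive *enabled* events: disabled
#' events are invisible to adjacency, and a latency window constrains but
#' never skips events.
#'
#' @param text Character: either the descriptor file content (single string or
#'   vector of lines).
#' @return A list of `bin_descriptor` objects, each with `bin_number`,
#'   `label`, `pre_items`, `home_item`, `post_items`.
#' @export
parse_bin_descriptors <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) %% 3L != 0L)
    stop("descriptor file must have three lines per bin (bin <k>, label, pattern)",
         call. = FALSE)
  out <- list()
  seen <- integer()
  for (i in seq(1L, length(lines), by = 3L)) {
    m <- regmatches(lines[i], regexec("^bin\\s+([0-9]+)$", lines[i]))[[1]]
    if (length(m) != 2L)
      stop("expected 'bin <k>' at descriptor line ", i, ", found: ", lines[i],
           call. = FALSE)
    bin_number <- as.integer(m[2])
    if (bin_number %in% seen)
      stop("bin ", bin_number, ": duplicate bin number", call. = FALSE)
    seen <- c(seen, bin_number)
    d <- parse_bin_pattern(lines[i + 2L], bin_number)
    d$label <- lines[i + 1L]
    out[[length(out) + 1L]] <- d
  }
  out
}

#' Read bin descriptors from a file
#' @param path Path to a bin-descriptor text file.
#' @return See [parse_bin_descriptors()].
#' @export
read_bin_descriptors <- function(path) {
  parse_bin_descriptors(readLines(path))
}

# parse one pattern line into a bin_descriptor
parse_bin_pattern <- function(pattern, bin_number) {
  # normalize typographic variants: en-dash in t<a-b>, invisible separators
  raw <- gsub("–", "-", pattern)
  raw <- gsub("[⁡​[:space:]]", "", raw)
  err <- function(pos, msg)
    stop(sprintf("bin %d: %s at character %d of pattern", bin_number, msg, pos),
         call. = FALSE)

  # split top level on '.', which must occur between items (outside braces)
  depth <- 0L
  dots <- integer()
  chars <- strsplit(raw, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "{") depth <- depth + 1L
    else if (chars[i] == "}") depth <- depth - 1L
    else if (chars[i] == "." && depth == 0L) dots <- c(dots, i)
    if (depth < 0L) err(i, "unbalanced '}'")
  }
  if (depth != 0L) err(length(chars), "unbalanced '{'")
  if (length(dots) == 0L) err(1L, "pattern must contain exactly one '.' (none found)")
  if (length(dots) > 1L) err(dots[2], "pattern must contain exactly one '.' (second found)")

  pre_str <- substr(raw, 1L, dots - 1L)
  rest <- substr(raw, dots + 1L, nchar(raw))
  pre_items <- parse_items(pre_str, bin_number, offset = 0L)
  rest_items <- parse_items(rest, bin_number, offset = dots)
  if (length(rest_items) == 0L) err(dots, "missing home item after '.'")
  home <- rest_items[[1]]
  post_items <- rest_items[-1]

  # structural invariants
  if (length(pre_items) && !is.null(pre_items[[1]]$time_window))
    err(pre_items[[1]]$pos, "time window not allowed on the first pre-item")
  if (!is.null(home$time_window))
    err(home$pos, "time window not allowed on the home item")
  for (it in c(pre_items, list(home)))
    if (!is.null(it$rt_name)) err(it$pos, "rt capture only allowed on post-items")

  structure(list(bin_number = bin_number, label = "",
                 pre_items = pre_items, home_item = home,
                 post_items = post_items),
            class = "bin_descriptor")
}

# parse a run of {...}{...} items; offset = character offset for error messages
parse_items <- function(s, bin_number, offset) {
  err <- function(pos, msg)
    stop(sprintf("bin %d: %s at character %d of pattern", bin_number, msg,
                 pos + offset), call. = FALSE)
  items <- list()
  pos <- 1L
  while (pos <= nchar(s)) {
    if (substr(s, pos, pos) != "{") err(pos, "expected '{'")
    close <- pos
    depth <- 0L
    repeat {
      ch <- substr(s, close, close)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") { depth <- depth - 1L; if (depth == 0L) break }
      close <- close + 1L
      if (close > nchar(s)) err(pos, "unbalanced '{'")
    }
    body <- substr(s, pos + 1L, close - 1L)
    items[[length(items) + 1L]] <- parse_item_body(body, bin_number, pos + offset)
    pos <- close + 1L
  }
  items
}

parse_item_body <- function(body, bin_number, pos) {
  err <- function(msg)
    stop(sprintf("bin %d: %s at character %d of pattern", bin_number, msg, pos),
         call. = FALSE)
  tw <- NULL
  m <- regmatches(body, regexec("^t<([0-9.]+)-([0-9.]+)>", body))[[1]]
  if (length(m) == 3L) {
    tw <- c(as.numeric(m[2]), as.numeric(m[3]))
    if (tw[1] > tw[2]) err(sprintf("time window min %g > max %g", tw[1], tw[2]))
    body <- substr(body, nchar(m[1]) + 1L, nchar(body))
  } else if (startsWith(body, "t<")) {
    err("malformed time condition")
  }
  rt_name <- NULL
  m <- regmatches(body, regexec(':rt<"([^"]*)">$', body))[[1]]
  if (length(m) == 2L) {
    rt_name <- m[2]
    body <- substr(body, 1L, nchar(body) - nchar(m[1]))
  }
  if (!nzchar(body)) err("empty code list")
  if (!grepl("^-?[0-9]+(;-?[0-9]+)*$", body)) err("malformed code list")
  codes <- as.integer(strsplit(body, ";", fixed = TRUE)[[1]])
  list(codes = codes, time_window = tw, rt_name = rt_name, pos = pos)
}

# Try to match descriptor d with its home item at enabled-position p.
# en: item indices of enabled events, onset: onsets (s) aligned with ev table.
# Returns NULL on failure, else the item indices matched by the post items.
match_descriptor_at <- function(codes, onsets, en, p, d) {
  k <- length(d$pre_items); l <- length(d$post_items)
  if (p - k < 1L || p + l > length(en)) return(NULL)
  if (!(codes[en[p]] %in% d$home_item$codes)) return(NULL)
  for (j in seq_len(k)) {
    idx <- en[p - k + j - 1L]
    it <- d$pre_items[[j]]
    if (!(codes[idx] %in% it$codes)) return(NULL)
    if (!is.null(it$time_window)) {
      prev <- en[p - k + j - 2L]
      dt_ms <- (onsets[idx] - onsets[prev]) * 1000
      if (dt_ms < it$time_window[1] - 1e-9 || dt_ms > it$time_window[2] + 1e-9)
        return(NULL)
    }
  }
  post_idx <- integer(l)
  for (j in seq_len(l)) {
    idx <- en[p + j]
    it <- d$post_items[[j]]
    if (!(codes[idx] %in% it$codes)) return(NULL)
    if (!is.null(it$time_window)) {
      prev <- if (j == 1L) en[p] else en[p + j - 1L]
      dt_ms <- (onsets[idx] - onsets[prev]) * 1000
      if (dt_ms < it$time_window[1] - 1e-9 || dt_ms > it$time_window[2] + 1e-9)
        return(NULL)
    }
    post_idx[j] <- idx
  }
  post_idx
}

#' Assign events to bins by descriptor matching
#'
#' For every enabled event and every descriptor, tests whether the event
#' matches the descriptor's home item with its pre and post items matching the
#' respectively adjacent enabled events (and every latency window satisfied);
#' on a full match the descriptor's bin number is appended to the event's bin
#' list. Disabled events are invisible to adjacency. An event may collect
#' several bins, and matches for different home events may share flanking
#' events. Previously assigned bins are cleared first, so reruns are
#' reproducible; finding no match is not an error.
#'
#' @param ev An `erp_eventlist`.
#' @param descriptors List of `bin_descriptor` from [parse_bin_descriptors()].
#' @return The event list with bins assigned.
#' @export
assign_bins <- function(ev, descriptors) {
  stopifnot(inherits(ev, "erp_eventlist"))
  e <- ev$events
  e$bins <- rep(list(integer()), nrow(e))
  en <- which(e$enabled)
  if (length(en)) {
    for (d in descriptors) {
      for (p in seq_along(en)) {
        if (!is.null(match_descriptor_at(e$code, e$onset, en, p, d))) {
          i <- en[p]
          e$bins[[i]] <- c(e$bins[[i]], d$bin_number)
        }
      }
    }
  }
  ev$events <- e
  ev
}

#' Extract captured reaction times
#'
#' After [assign_bins()] with the same descriptors, returns one row per
#' (home event, rt capture): the bin number, the home event's item index, the
#' capture name, and the latency of the captured event relative to the home
#' event in ms. Descriptors without captures contribute no rows.
#'
#' @inheritParams assign_bins
#' @return A tibble with columns `bin_number`, `item`, `rt_name`, `rt_ms`,
#'   in event order.
#' @export
extract_rts <- function(ev, descriptors) {
  stopifnot(inherits(ev, "erp_eventlist"))
  e <- ev$events
  en <- which(e$enabled)
  rows <- list()
  for (p in seq_along(en)) {
    for (d in descriptors) {
      has_rt <- any(!vapply(d$post_items, function(it) is.null(it$rt_name), TRUE))
      if (!has_rt) next
      post_idx <- match_descriptor_at(e$code, e$onset, en, p, d)
      if (is.null(post_idx)) next
      home <- en[p]
      for (j in seq_along(d$post_items)) {
        it <- d$post_items[[j]]
        if (is.null(it$rt_name)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          bin_number = d$bin_number,
          item = e$item[home],
          rt_name = it$rt_name,
          rt_ms = (e$onset[post_idx[j]] - e$onset[home]) * 1000
        )
      }
    }
  }
  if (!length(rows))
    return(tibble::tibble(bin_number = integer(), item = integer(),
                          rt_name = character(), rt_ms = numeric()))
  dplyr::bind_rows(rows)
}
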