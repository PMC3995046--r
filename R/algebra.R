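#' The channel/bin equation language
#'
#' Re-referencing, bipolar EOG derivation, interpolation of bad electrodes,
#' difference waves and other recombinations are all expressed as small,
#' transparent equations instead of opaque coefficient matrices:
#'
#' ```
#' chan33 = chan27 - chan26 label VEOG
#' newchan1 = sqrt(chan1^2 + chan2^2) + 5
#' chan14 = avgchan(10,12,16,18)
#' bin3 = bin2 - bin1 label Oddball-Minus-Standard
#' newbin3 = bin1@Left + bin2@Right
#' ```
#'
#' One equation per line; blank lines and `#` comments are ignored; an
#' optional `label <text>` suffix names the created channel or bin. Operands
#' are `chanN` in channel equations and `binN` in bin equations (a bin operand
#' may carry an `@GroupName` electrode-group suffix); literals, `+ - * / ^`
#' (right-associative power), unary minus, parentheses, `sqrt`, `abs` and
#' `avgchan(range-list)` (channel equations only; ranges like `1:32,38:50`)
#' are available. The typographic minus and circumflex (as they appear in
#' print) are accepted alongside their ASCII forms.
#'
#' Evaluation semantics: equations run sequentially against a working copy.
#' A `chanK`/`binK` target replaces axis element K in place (appending when
#' K is one past the end), and its right-hand side sees the results of
#' earlier equations. A `newchanK`/`newbinK` target evaluates its right-hand
#' side against a snapshot taken before the equation list ran — so a whole
#' montage can be re-referenced consistently (`newchan1=chan1-avgchan(...)`,
#' `newchan2=...`) without later equations seeing half-re-referenced data —
#' and replaces element K (or appends when K is one past the end).
#' Division by zero is an error: voltage data must stay finite.
#'
#' @param text Equation file content: a single string or a vector of lines.
#' @return A list of `erp_equation` objects (target kind and index, parse
#'   tree, optional label, source line number).
#' @export
parse_equations <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    eq <- tryCatch(parse_equation_line(ln),
                   error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                            call. = FALSE))
    eq$line <- i
    out[[length(out) + 1L]] <- eq
  }
  out
}

parse_equation_line <- function(ln) {
  # pull off the label suffix before touching whitespace
  label <- NULL
  m <- regmatches(ln, regexec("^(.*?)\\s+label\\s+(.+)$", ln))[[1]]
  if (length(m) == 3L) { ln <- m[2]; label <- m[3] }
  ln <- gsub("−", "-", ln)   # typographic minus
  ln <- gsub("ˆ", "^", ln)   # modifier circumflex as printed
  ln <- gsub("⁡", "", ln)    # invisible function-application mark
  ln <- gsub("[[:space:]]", "", ln)
  eqpos <- regexpr("=", ln, fixed = TRUE)
  if (eqpos < 0) stop("missing '='")
  lhs <- substr(ln, 1L, eqpos - 1L)
  rhs <- substr(ln, eqpos + 1L, nchar(ln))
  tm <- regmatches(lhs, regexec("^(newchan|chan|newbin|bin)([0-9]+)$", lhs))[[1]]
  if (length(tm) != 3L) stop("target must be chanN, newchanN, binN or newbinN, got '", lhs, "'")
  target_kind <- tm[2]
  target_index <- as.integer(tm[3])
  if (target_index < 1L) stop("target index must be positive")
  ast <- parse_expression(rhs)
  context <- if (target_kind %in% c("chan", "newchan")) "chan" else "bin"
  check_equation_context(ast, context)
  structure(list(target_kind = target_kind, target_index = target_index,
                 ast = ast, label = label, text = ln),
            class = "erp_equation")
}

# --- tokenizer ---------------------------------------------------------------

tokenize_expr <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    rest <- substr(s, i, n)
    if (grepl("^[0-9]", ch) || (ch == "." && grepl("^\\.[0-9]", rest))) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", rest))
      toks[[length(toks) + 1L]] <- list(t = "num", v = as.numeric(m), pos = i)
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      toks[[length(toks) + 1L]] <- list(t = "name", v = m, pos = i)
      i <- i + nchar(m)
    } else if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",", ":", "@")) {
      toks[[length(toks) + 1L]] <- list(t = ch, v = ch, pos = i)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i)
    }
  }
  toks
}

# --- recursive-descent parser ------------------------------------------------
# expr   := term (('+'|'-') term)*
# term   := factor (('*'|'/') factor)*
# factor := unary ('^' factor)?              right-associative power
# unary  := ('-'|'+')? primary
# primary:= NUM | operand['@'NAME] | sqrt/abs '(' expr ')'
#         | avgchan '(' ranges ')' | '(' expr ')'

parse_expression <- function(s) {
  toks <- tokenize_expr(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { tk <- toks[[pos]]; pos <<- pos + 1L; tk }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$t != type)
      stop("expected '", type, "'", if (!is.null(tk)) paste0(" at position ", tk$pos) else " at end")
    advance()
  }

  parse_ranges <- function() {
    ranges <- list()
    repeat {
      a <- expect("num")$v
      if (a != round(a)) stop("range bounds must be integers")
      tk <- peek()
      if (!is.null(tk) && tk$t == ":") {
        advance()
        b <- expect("num")$v
        if (b != round(b) || b < a) stop("malformed range ", a, ":", b)
        ranges[[length(ranges) + 1L]] <- c(as.integer(a), as.integer(b))
      } else {
        ranges[[length(ranges) + 1L]] <- c(as.integer(a), as.integer(a))
      }
      tk <- peek()
      if (is.null(tk) || tk$t != ",") break
      advance()
    }
    ranges
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) stop("unexpected end of expression")
    if (tk$t == "num") { advance(); return(list(t = "num", v = tk$v)) }
    if (tk$t == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    if (tk$t == "name") {
      advance()
      nm <- tk$v
      rm_ <- regmatches(nm, regexec("^(chan|bin)([0-9]+)$", nm))[[1]]
      if (length(rm_) == 3L) {
        node <- list(t = "ref", kind = rm_[2], index = as.integer(rm_[3]), group = NULL)
        nxt <- peek()
        if (!is.null(nxt) && nxt$t == "@") {
          advance()
          g <- expect("name")$v
          if (node$kind != "bin") stop("electrode groups apply to bin operands only")
          node$group <- g
        }
        return(node)
      }
      if (nm %in% c("sqrt", "abs")) {
        expect("(")
        a <- parse_expr()
        expect(")")
        return(list(t = "call", fn = nm, a = a))
      }
      if (nm == "avgchan") {
        expect("(")
        ranges <- parse_ranges()
        expect(")")
        return(list(t = "avgchan", ranges = ranges))
      }
      stop("unknown function or operand '", nm, "'")
    }
    stop("unexpected token '", tk$v, "' at position ", tk$pos)
  }

  parse_unary <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$t %in% c("-", "+")) {
      advance()
      a <- parse_factor_tail(parse_unary())
      if (tk$t == "+") return(a)
      return(list(t = "neg", a = a))
    }
    parse_primary()
  }

  parse_factor_tail <- function(base) {
    force(base)      # must consume the operand before peeking at '^'
    tk <- peek()
    if (!is.null(tk) && tk$t == "^") {
      advance()
      list(t = "bin2", op = "^", a = base, b = parse_factor())
    } else base
  }

  parse_factor <- function() parse_factor_tail(parse_unary())

  parse_term <- function() {
    node <- parse_factor()
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$t %in% c("*", "/"))) break
      advance()
      node <- list(t = "bin2", op = tk$t, a = node, b = parse_factor())
    }
    node
  }

  parse_expr <- function() {
    node <- parse_term()
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$t %in% c("+", "-"))) break
      advance()
      node <- list(t = "bin2", op = tk$t, a = node, b = parse_term())
    }
    node
  }

  node <- parse_expr()
  tk <- peek()
  if (!is.null(tk)) stop("unexpected token '", tk$v, "' at position ", tk$pos)
  node
}

check_equation_context <- function(node, context) {
  walk <- function(n) {
    switch(n$t,
      ref = {
        if (n$kind != context)
          stop(n$kind, "N operands are not allowed in ", context, " equations")
      },
      avgchan = {
        if (context != "chan")
          stop("avgchan() is only allowed in channel equations")
      },
      num = NULL,
      neg = walk(n$a),
      call = walk(n$a),
      bin2 = { walk(n$a); walk(n$b) })
    invisible(NULL)
  }
  walk(node)
}

#' Pretty-print a parsed equation back to canonical text
#'
#' Re-parsing the returned text yields an identical parse tree.
#'
#' @param eq An `erp_equation`.
#' @return Character scalar.
#' @export
deparse_equation <- function(eq) {
  fmt <- function(n) {
    switch(n$t,
      num = format(n$v, digits = 15),
      ref = paste0(n$kind, n$index, if (!is.null(n$group)) paste0("@", n$group)),
      neg = paste0("(-", fmt(n$a), ")"),
      call = paste0(n$fn, "(", fmt(n$a), ")"),
      avgchan = paste0("avgchan(", paste(vapply(n$ranges, function(r)
        if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], ":", r[2]), ""),
        collapse = ","), ")"),
      bin2 = paste0("(", fmt(n$a), n$op, fmt(n$b), ")"))
  }
  paste0(eq$target_kind, eq$target_index, "=", fmt(eq$ast),
         if (!is.null(eq$label)) paste0(" label ", eq$label) else "")
}

# --- evaluation --------------------------------------------------------------

# ctx: list(get = function(index, group) value-array, n = axis length)
eval_equation_ast <- function(node, ctx) {
  ev <- function(n) {
    switch(n$t,
      num = n$v,
      ref = ctx$get(n$index, n$group),
      neg = -ev(n$a),
      call = {
        v <- do.call(n$fn, list(ev(n$a)))
        if (any(!is.finite(v)))
          stop(n$fn, "() produced non-finite values", call. = FALSE)
        v
      },
      avgchan = {
        idx <- unlist(lapply(n$ranges, function(r) seq(r[1], r[2])))
        vals <- lapply(idx, function(k) ctx$get(k, NULL))
        Reduce(`+`, vals) / length(vals)
      },
      bin2 = {
        a <- ev(n$a); b <- ev(n$b)
        if (n$op == "/" && any(b == 0))
          stop("division by zero in equation", call. = FALSE)
        switch(n$op, `+` = a + b, `-` = a - b, `*` = a * b, `/` = a / b,
               `^` = a ^ b)
      })
  }
  ev(node)
}

# channel-data accessors shared by equation evaluation; values are
# vector (continuous), epochs x samples, or bins x samples matrices
get_chan_values <- function(obj, k) {
  if (k < 1L) stop("channel index must be positive", call. = FALSE)
  nc <- n_chan_of(obj)
  if (k > nc) stop("reference to nonexistent channel ", k, call. = FALSE)
  if (inherits(obj, "erp_continuous")) obj$data[k, ]
  else matrix(obj$data[, k, ], nrow = dim(obj$data)[1])
}

n_chan_of <- function(obj) {
  if (inherits(obj, "erp_continuous")) nrow(obj$data) else dim(obj$data)[2]
}

set_chan_values <- function(obj, k, v, label = NULL) {
  nc <- n_chan_of(obj)
  if (inherits(obj, "erp_continuous")) {
    if (length(v) == 1L) v <- rep(v, ncol(obj$data))
    if (k <= nc) obj$data[k, ] <- v
    else { obj$data <- rbind(obj$data, v); rownames(obj$data) <- NULL }
  } else {
    d <- dim(obj$data)
    if (length(v) == 1L) v <- matrix(v, d[1], d[3])
    if (k <= nc) obj$data[, k, ] <- v
    else {
      nd <- array(0, dim = c(d[1], d[2] + 1L, d[3]))
      nd[, seq_len(d[2]), ] <- obj$data
      nd[, d[2] + 1L, ] <- v
      obj$data <- nd
      if (inherits(obj, "erp_epochs"))
        obj$chan_marks <- cbind(obj$chan_marks, FALSE)
    }
  }
  if (k > nc) obj$chan_labels <- c(obj$chan_labels, if (is.null(label)) paste0("ch", k) else label)
  else if (!is.null(label)) obj$chan_labels[k] <- label
  obj
}

#' Apply channel equations to EEG or ERP data
#'
#' Works identically on continuous EEG, epoched EEG and averaged ERP sets;
#' see [parse_equations()] for the language and evaluation semantics.
#'
#' @param obj An `erp_continuous`, `erp_epochs` or `erp_set`.
#' @param eqs Equations from [parse_equations()] (channel targets only).
#' @return The same kind of object with equations applied.
#' @export
apply_channel_ops <- function(obj, eqs) {
  stopifnot(inherits(obj, c("erp_continuous", "erp_epochs", "erp_set")))
  snapshot <- obj
  for (eq in eqs) {
    if (!eq$target_kind %in% c("chan", "newchan"))
      stop("equation line ", eq$line %||% "?", ": bin equation applied as channel operation",
           call. = FALSE)
    source_obj <- if (eq$target_kind == "newchan") snapshot else obj
    ctx <- list(get = function(k, group) get_chan_values(source_obj, k))
    v <- eval_equation_ast(eq$ast, ctx)
    k <- eq$target_index
    nc <- n_chan_of(obj)
    if (k > nc + 1L)
      stop(eq$target_kind, k, ": index gap (object has ", nc, " channels)", call. = FALSE)
    obj <- set_chan_values(obj, k, v, label = eq$label)
  }
  obj <- assert_finite(obj)
  cmd <- paste(vapply(eqs, deparse_equation, ""), collapse = "\n")
  append_history(obj, sprintf("apply_channel_ops(x, parse_equations(%s))", deparse(cmd)))
}

#' Generate re-referencing equations
#'
#' Writes, for each channel to re-reference, the equation
#' `newchan<k>=chan<k>-avgchan(<reference ranges>)`. The equations are
#' returned as editable text and are not applied, so the re-referencing
#' scheme stays fully visible to (and editable by) the user before it runs.
#'
#' @param channels Integer vector of channel indices to re-reference.
#' @param reference Reference channels: a range-list string like
#'   `"1:32,38:50"` or an integer vector (compressed to ranges).
#' @return Character vector of equations, one per channel; parseable by
#'   [parse_equations()].
#' @export
reference_assistant <- function(channels, reference) {
  if (!length(channels)) stop("no channels to re-reference", call. = FALSE)
  if (!length(reference)) stop("no reference channels", call. = FALSE)
  ref_str <- if (is.character(reference)) {
    gsub("[[:space:]]", "", paste(reference, collapse = ","))
  } else {
    r <- sort(unique(as.integer(reference)))
    brk <- c(0L, which(diff(r) != 1L), length(r))
    paste(vapply(seq_len(length(brk) - 1L), function(i) {
      a <- r[brk[i] + 1L]; b <- r[brk[i + 1L]]
      if (a == b) as.character(a) else paste0(a, ":", b)
    }, ""), collapse = ",")
  }
  sprintf("newchan%d=chan%d-avgchan(%s)", channels, channels, ref_str)
}

#' Electrode groups for bin operations
#'
#' Parses group definitions, one per line: `Name: 1,2,3`. Groups let one bin
#' equation combine different electrodes for different bins (the
#' contralateral-minus-ipsilateral idiom of N2pc and lateralized readiness
#' potential analyses): `bin1@Left + bin2@Right` pairs the i-th channel of
#' `Left` with the i-th channel of `Right`.
#'
#' @param text Group file content (string or vector of lines).
#' @return Named list of integer channel-index vectors.
#' @export
parse_electrode_groups <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  groups <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([0-9, ]+)$", ln))[[1]]
    if (length(m) != 3L) stop("line ", i, ": malformed group definition", call. = FALSE)
    groups[[m[2]]] <- as.integer(strsplit(gsub(" ", "", m[3]), ",")[[1]])
  }
  groups
}

collect_refs <- function(node) {
  out <- list()
  walk <- function(n) {
    switch(n$t,
      ref = out[[length(out) + 1L]] <<- n,
      neg = walk(n$a), call = walk(n$a),
      bin2 = { walk(n$a); walk(n$b) },
      NULL)
  }
  walk(node)
  out
}

#' Apply bin equations to an ERP set
#'
#' Same sequential semantics as [apply_channel_ops()], over the bin axis:
#' `binK` targets replace in place and see earlier results, `newbinK` targets
#' evaluate against the pre-call snapshot and replace or append. A derived
#' bin's accepted-trial count is the minimum over its operand bins.
#'
#' When any equation uses electrode groups, all groups used must have equal
#' length, the returned set's channel axis becomes the first group's channels
#' (with those channels' labels), existing bins are carried subset to those
#' channels, and grouped operands are read from the pre-call snapshot.
#'
#' @param erp An `erp_set`.
#' @param eqs Equations from [parse_equations()] (bin targets only).
#' @param groups Named list from [parse_electrode_groups()].
#' @return The recombined `erp_set`.
#' @export
apply_bin_ops <- function(erp, eqs, groups = list()) {
  stopifnot(inherits(erp, "erp_set"))
  snapshot <- erp
  used_groups <- unique(unlist(lapply(eqs, function(eq)
    vapply(Filter(function(r) !is.null(r$group), collect_refs(eq$ast)),
           function(r) r$group, ""))))
  grouped <- length(used_groups) > 0L
  if (grouped) {
    missing_g <- setdiff(used_groups, names(groups))
    if (length(missing_g))
      stop("undefined electrode group(s): ", paste(missing_g, collapse = ", "),
           call. = FALSE)
    glens <- lengths(groups[used_groups])
    if (length(unique(glens)) != 1L)
      stop("group length mismatch: ", paste(used_groups, glens, collapse = ", "),
           call. = FALSE)
    g1 <- groups[[used_groups[1]]]
    if (any(unlist(groups[used_groups]) > dim(erp$data)[2]))
      stop("group channel index out of range", call. = FALSE)
    # restrict the working set to the first group's channels
    erp$data <- erp$data[, g1, , drop = FALSE]
    erp$chan_labels <- snapshot$chan_labels[g1]
  }
  get_bin <- function(src, k, group) {
    nb <- dim(src$data)[1]
    if (k < 1L || k > nb) stop("reference to nonexistent bin ", k, call. = FALSE)
    if (!is.null(group)) {
      gi <- groups[[group]]
      matrix(snapshot$data[k, gi, ], nrow = length(gi))
    } else {
      m <- matrix(src$data[k, , ], nrow = dim(src$data)[2])
      if (grouped && nrow(m) != length(groups[[used_groups[1]]]))
        stop("mixing grouped and ungrouped operands of different widths", call. = FALSE)
      m
    }
  }
  for (eq in eqs) {
    if (!eq$target_kind %in% c("bin", "newbin"))
      stop("equation line ", eq$line %||% "?", ": channel equation applied as bin operation",
           call. = FALSE)
    src <- if (eq$target_kind == "newbin") snapshot else erp
    ctx <- list(get = function(k, group) get_bin(src, k, group))
    v <- eval_equation_ast(eq$ast, ctx)
    k <- eq$target_index
    nb <- dim(erp$data)[1]
    if (k > nb + 1L)
      stop(eq$target_kind, k, ": index gap (set has ", nb, " bins)", call. = FALSE)
    if (length(v) == 1L) v <- matrix(v, dim(erp$data)[2], dim(erp$data)[3])
    # derived-bin accounting: most conservative operand count
    ops <- vapply(collect_refs(eq$ast), function(r) r$index, 0L)
    n_acc <- if (length(ops)) min(src$counts$n_accepted[ops]) else 0L
    if (k <= nb) {
      erp$data[k, , ] <- v
      erp$counts$n_accepted[k] <- n_acc
      if (!is.null(eq$label)) erp$bin_labels[k] <- eq$label
    } else {
      d <- dim(erp$data)
      nd <- array(0, dim = c(d[1] + 1L, d[2], d[3]))
      nd[seq_len(d[1]), , ] <- erp$data
      nd[d[1] + 1L, , ] <- v
      erp$data <- nd
      erp$bin_labels <- c(erp$bin_labels,
                          if (is.null(eq$label)) paste0("bin", k) else eq$label)
      erp$counts <- dplyr::bind_rows(erp$counts, tibble::tibble(
        bin = k, n_accepted = as.integer(n_acc), n_rejected = 0L))
      erp$rejected_by_flag <- rbind(erp$rejected_by_flag, rep(0L, 8L))
    }
  }
  erp <- assert_finite(erp)
  cmd <- paste(vapply(eqs, deparse_equation, ""), collapse = "\n")
  append_history(erp, sprintf("apply_bin_ops(x, parse_equations(%s))", deparse(cmd)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
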