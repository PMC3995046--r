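#' Run a processing pipeline from a declarative configuration
#'
#' Executes an ordered list of commands, each a `list(command = <name>,
#' params = <named list>)`, threading the current object (continuous EEG,
#' epochs or ERP set) from step to step exactly as an interactive session
#' would, and logging parameters and counts along the way. Every step appends
#' to the object's command history, so the processed result documents how it
#' was made. Available commands:
#'
#' `simulate`, `eventlist_export`, `eventlist_import`, `binlister`, `epoch`,
#' `baseline`, `artifact`, `reject_continuous`, `chanops`, `binops`,
#' `filter`, `average`, `grandavg`, `measure`, `erp_export`, `plot`.
#'
#' An unknown command or invalid parameter stops the pipeline with an error
#' naming the failing stage; use [run_pipeline_cli()] semantics (exit status)
#' via the bundled `inst/cli/erp.R` script when driving from a shell.
#'
#' @param steps List of steps; each `list(command =, params = list(...))`.
#' @param input Optional starting object (when the first step is not
#'   `simulate` or an import).
#' @param log Print a log line per step?
#' @return The final object of the pipeline.
#' @export
run_pipeline <- function(steps, input = NULL, log = TRUE) {
  x <- input
  known <- c("simulate", "eventlist_export", "eventlist_import", "binlister",
             "epoch", "baseline", "artifact", "reject_continuous", "chanops",
             "binops", "filter", "average", "grandavg", "measure",
             "erp_export", "plot")
  say <- function(...) if (log) message(sprintf(...))
  for (si in seq_along(steps)) {
    st <- steps[[si]]
    cmd <- st$command
    p <- st$params %||% list()
    if (is.null(cmd) || !cmd %in% known)
      stop(sprintf("stage %d: unknown command '%s'; valid commands: %s",
                   si, cmd %||% "<missing>", paste(known, collapse = ", ")),
           call. = FALSE)
    x <- tryCatch(switch(cmd,
      simulate = {
        cfg <- do.call(sim_config, p)
        sim <- simulate_oddball(cfg)
        say("simulate: %d trials, %d channels, %.1f s, seed %d",
            cfg$n_trials, length(cfg$chan_labels),
            ncol(sim$eeg$data) / cfg$srate, cfg$seed)
        attr(sim$eeg, "truth") <- sim$truth
        sim$eeg
      },
      eventlist_export = {
        write_eventlist_text(x$events, p$path)
        say("eventlist_export: %d events -> %s", n_events(x$events), p$path)
        x
      },
      eventlist_import = {
        x$events <- read_eventlist_text(p$path)
        say("eventlist_import: %d events <- %s", n_events(x$events), p$path)
        x
      },
      binlister = {
        descr <- if (!is.null(p$path)) read_bin_descriptors(p$path)
                 else parse_bin_descriptors(p$text)
        x$events <- assign_bins(x$events, descr)
        n_assigned <- sum(lengths(x$events$events$bins) > 0)
        say("binlister: %d descriptors, %d events assigned",
            length(descr), n_assigned)
        x
      },
      epoch = {
        ep <- extract_epochs(x, p$tmin, p$tmax)
        say("epoch: %d epochs extracted, %d skipped", dim(ep$data)[1],
            ep$n_skipped)
        ep
      },
      baseline = {
        baseline_correct(x, p$start %||% x$tmin, p$end %||% 0)
      },
      artifact = {
        spec <- do.call(detector_spec, p)
        ep <- detect_artifacts(x, spec)
        say("artifact (%s): %d/%d epochs flagged", spec$algorithm,
            sum(ep$flags[, 1]), dim(ep$data)[1])
        ep
      },
      reject_continuous = {
        do.call(reject_continuous, c(list(x), p))
      },
      chanops = {
        eqs <- if (!is.null(p$path)) parse_equations(readLines(p$path))
               else parse_equations(p$text)
        say("chanops: %d equations", length(eqs))
        apply_channel_ops(x, eqs)
      },
      binops = {
        eqs <- if (!is.null(p$path)) parse_equations(readLines(p$path))
               else parse_equations(p$text)
        groups <- if (!is.null(p$groups_path))
          parse_electrode_groups(readLines(p$groups_path))
        else if (!is.null(p$groups_text)) parse_electrode_groups(p$groups_text)
        else list()
        say("binops: %d equations, %d groups", length(eqs), length(groups))
        apply_bin_ops(x, eqs, groups)
      },
      filter = {
        spec <- do.call(filter_spec, p)
        say("filter: %s %s Hz (%s)", spec$mode,
            paste(spec$half_amp, collapse = "-"), spec$kind)
        apply_filter(x, spec)
      },
      average = {
        erp <- do.call(average_epochs, c(list(x), p))
        say("average: %d bins, accepted %s", nrow(erp$counts),
            paste(erp$counts$n_accepted, collapse = "/"))
        erp
      },
      grandavg = {
        grand_average(x, weighted = isTRUE(p$weighted))
      },
      measure = {
        tbl <- do.call(measure_erps, c(list(x), p))
        say("measure: %d values", nrow(tbl))
        attr(x, "measurements") <- tbl
        x
      },
      erp_export = {
        write_erp_text(x, p$path)
        say("erp_export: -> %s", p$path)
        x
      },
      plot = {
        do.call(plot_waveforms, c(list(x), p))
        x
      }),
      error = function(e)
        stop(sprintf("stage %d (%s): %s", si, cmd, conditionMessage(e)),
             call. = FALSE))
  }
  x
}

#' Plot averaged waveforms to a file
#'
#' One panel per non-overlaid axis element with the other axis overlaid as
#' colored traces; classic ERP plotting conventions, including optional
#' negative-up voltage axes. Output format follows the file extension
#' (pdf/png/svg via [ggplot2::ggsave()]).
#'
#' @param erp An `erp_set`.
#' @param bins,channels Bin numbers and channel labels/indices to include
#'   (defaults: all).
#' @param overlay `"bins"` (default) or `"channels"`: which axis becomes
#'   overlaid traces; the other defines the panels.
#' @param path Output image path.
#' @param negative_up Plot negative voltage upward (the traditional ERP
#'   orientation)?
#' @return The ggplot object, invisibly (after writing `path` if given).
#' @export
plot_waveforms <- function(erp, bins = NULL, channels = NULL,
                           overlay = c("bins", "channels"), path = NULL,
                           negative_up = FALSE) {
  stopifnot(inherits(erp, "erp_set"))
  overlay <- match.arg(overlay)
  if (is.null(bins)) bins <- seq_len(dim(erp$data)[1])
  if (is.null(channels)) channels <- erp$chan_labels
  if (is.numeric(channels)) channels <- erp$chan_labels[channels]
  if (!length(bins) || !length(channels)) stop("empty selection", call. = FALSE)
  if (any(!channels %in% erp$chan_labels))
    stop("unknown channel: ",
         paste(setdiff(channels, erp$chan_labels), collapse = ", "), call. = FALSE)
  if (any(bins < 1 | bins > dim(erp$data)[1])) stop("unknown bin", call. = FALSE)
  df <- as_tibble(erp)
  df <- df[df$bin %in% bins & df$channel %in% channels, ]
  df$bin_label <- factor(df$bin_label, levels = unique(df$bin_label))
  df$channel <- factor(df$channel, levels = channels)
  g <- if (overlay == "bins") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                     color = .data$bin_label)) +
      ggplot2::facet_wrap(~channel)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                     color = .data$channel)) +
      ggplot2::facet_wrap(~bin_label)
  }
  g <- g + ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)", color = NULL) +
    ggplot2::theme_minimal()
  if (negative_up) g <- g + ggplot2::scale_y_reverse()
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 8, height = 5)
  invisible(g)
}

#' @export
#' @rdname plot_waveforms
#' @param object,... For the `autoplot` method: the `erp_set` and arguments
#'   passed on to `plot_waveforms()`.
autoplot.erp_set <- function(object, ...) plot_waveforms(object, ...)
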