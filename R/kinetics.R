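# Rebinding-time and rebinding-rate statistics: per-event-list summaries and
# aggregation across (distance, construct) sweep cells.

#' Rebinding times from an ordered event list
#'
#' The rebinding time is the interval between a detachment and the next
#' binding event: `t_start[i+1] - t_end[i]` for consecutive event pairs.
#' Its reciprocal mean is the rebinding rate, the on-rate proxy.
#'
#' @param events A `binding_events` table (or any data frame with `t_start`
#'   and `t_end`), time-ordered and non-overlapping.
#' @return Numeric vector of rebinding times, s (empty for fewer than two
#'   events).
#' @export
rebinding_times <- function(events) {
  n <- nrow(events)
  if (n < 2) return(numeric(0))
  if (is.unsorted(events$t_start))
    abort_runtime("events must be time-ordered", "trapkin_event_error")
  out <- events$t_start[-1] - events$t_end[-n]
  if (any(out < 0))
    abort_runtime("events overlap; rebinding times undefined", "trapkin_event_error")
  out
}

#' Convert between mean rebinding time and rebinding rate
#'
#' Exact reciprocals: a rate of 4.7 /s corresponds to a mean rebinding time
#' of 1/4.7 = 0.21 s.
#'
#' @param mean_time Mean rebinding time, s (> 0).
#' @param rate Rebinding rate, 1/s (> 0).
#' @return The reciprocal quantity.
#' @export
rate_from_mean_time <- function(mean_time) {
  if (any(!is.finite(mean_time)) || any(mean_time <= 0))
    abort_config("mean_time must be > 0")
  1 / mean_time
}

#' @rdname rate_from_mean_time
#' @export
time_from_rate <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    abort_config("rate must be > 0")
  1 / rate
}

#' Summary statistics of one event list
#'
#' Bound times and peak forces are taken from non-truncated events only;
#' rebinding intervals use every observed event start. With no usable events
#' the statistics are `NA` (undefined), never zero.
#'
#' @param events A `binding_events` table.
#' @return An `event_statistics` list: `rebinding_times`, `bound_times`,
#'   `peak_forces`, `mean_rebinding_time`, `rebinding_rate`, `n_events`.
#' @export
event_statistics <- function(events) {
  rb <- rebinding_times(events)
  keep <- !events$truncated
  mean_rb <- if (length(rb)) mean(rb) else NA_real_
  structure(list(
    rebinding_times = rb,
    bound_times = events$bound_time[keep],
    peak_forces = events$peak_force[keep],
    mean_rebinding_time = mean_rb,
    rebinding_rate = if (is.finite(mean_rb) && mean_rb > 0)
      rate_from_mean_time(mean_rb) else NA_real_,
    n_events = nrow(events)
  ), class = "event_statistics")
}

#' @export
print.event_statistics <- function(x, ...) {
  cat(sprintf(paste0("event_statistics: %d events; mean rebinding time %.3g s ",
                     "(rate %.3g /s); mean bound time %.3g s; mean peak force %.3g pN\n"),
              x$n_events, x$mean_rebinding_time, x$rebinding_rate,
              mean(x$bound_times), mean(x$peak_forces)))
  invisible(x)
}

#' Summarise a sweep of traces into distance-resolved statistics
#'
#' Detects events in every trace of a [generate_sweep()] collection (mode
#' chosen from the trace's dither setting, or forced via `mode`), pools
#' rebinding intervals within each (distance, construct) cell across repeats
#' (intervals never span a trace boundary), and returns per-cell
#' [event_statistics()] plus a tidy long-format table.
#'
#' @param sweep A `trace_sweep`.
#' @param cfg A [detection_config()].
#' @param mode `"auto"` (per-trace), `"stationary"`, `"dithered"`, or
#'   `"truth"` to use the simulator's ground-truth events.
#' @return A `sweep_result` with `cells` (list of `event_statistics`),
#'   `table` (long format: d_B_MT, construct, statistic, value, se, n) and
#'   metadata.
#' @export
summarize_sweep <- function(sweep, cfg = detection_config(),
                            mode = c("auto", "stationary", "dithered", "truth")) {
  stopifnot(inherits(sweep, "trace_sweep"))
  mode <- match.arg(mode)
  events_for <- function(trace) {
    if (mode == "truth") {
      te <- trace$true_events
      ev <- data.frame(t_start = te$bind_time, t_end = te$unbind_time,
                       bound_time = te$unbind_time - te$bind_time,
                       peak_force = NA_real_, polarity = NA_integer_,
                       mode = "truth", truncated = te$truncated)
      return(structure(ev, class = c("binding_events", "data.frame")))
    }
    use_dither <- switch(mode, auto = trace$config$dither$enabled,
                         stationary = FALSE, dithered = TRUE)
    if (use_dither) detect_events_dithered(trace, cfg)
    else detect_events(trace, cfg)
  }
  cells_meta <- sweep$cells
  key <- interaction(cells_meta$d_B_MT, cells_meta$construct, drop = TRUE)
  stats_by_cell <- lapply(split(seq_len(nrow(cells_meta)), key), function(idx) {
    evs <- lapply(sweep$traces[idx], events_for)
    pooled <- list(
      rebinding_times = unlist(lapply(evs, rebinding_times)),
      bound_times = unlist(lapply(evs, function(e) e$bound_time[!e$truncated])),
      peak_forces = unlist(lapply(evs, function(e) e$peak_force[!e$truncated])),
      n_events = sum(vapply(evs, nrow, integer(1)))
    )
    mean_rb <- if (length(pooled$rebinding_times)) mean(pooled$rebinding_times)
               else NA_real_
    pooled$mean_rebinding_time <- mean_rb
    pooled$rebinding_rate <- if (is.finite(mean_rb) && mean_rb > 0) 1 / mean_rb
                             else NA_real_
    pooled$d_B_MT <- cells_meta$d_B_MT[idx[1]]
    pooled$construct <- cells_meta$construct[idx[1]]
    class(pooled) <- "event_statistics"
    pooled
  })

  long <- do.call(rbind, lapply(stats_by_cell, function(s) {
    row <- function(stat, v) data.frame(
      d_B_MT = s$d_B_MT, construct = s$construct, statistic = stat,
      value = if (length(v)) mean(v) else NA_real_,
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
    rbind(row("rebinding_time", s$rebinding_times),
          row("bound_time", s$bound_times),
          row("peak_force", s$peak_forces),
          data.frame(d_B_MT = s$d_B_MT, construct = s$construct,
                     statistic = "rebinding_rate", value = s$rebinding_rate,
                     se = NA_real_, n = length(s$rebinding_times)))
  }))
  rownames(long) <- NULL
  structure(list(cells = stats_by_cell, table = long, mode = mode,
                 seed = sweep$seed, n_traces = length(sweep$traces)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result (%s detection): %d cell(s) from %d trace(s)\n",
              x$mode, length(x$cells), x$n_traces))
  rb <- x$table[x$table$statistic == "rebinding_time", ]
  if (nrow(rb)) {
    cat("mean rebinding time (s) by d_B-MT and construct:\n")
    print(utils::head(rb[, c("d_B_MT", "construct", "value", "se", "n")], 20),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) x$table

#' @export
plot.sweep_result <- function(x, statistic = "rebinding_time", ...) {
  tab <- x$table[x$table$statistic == statistic & is.finite(x$table$value), ]
  if (!nrow(tab)) {
    warning("no finite values to plot")
    return(invisible(x))
  }
  constructs <- unique(tab$construct)
  cols <- grDevices::hcl.colors(max(3, length(constructs)), "Dark 3")
  plot(range(tab$d_B_MT), range(tab$value), type = "n",
       xlab = "d_B-MT (nm)", ylab = statistic, ...)
  for (i in seq_along(constructs)) {
    sub <- tab[tab$construct == constructs[i], ]
    sub <- sub[order(sub$d_B_MT), ]
    graphics::lines(sub$d_B_MT, sub$value, type = "b", col = cols[i], pch = 16)
  }
  graphics::legend("topleft", legend = constructs, col = cols[seq_along(constructs)],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Histogram summaries of event statistics
#'
#' Bins the rebinding-time, bound-time and (when supplied) latency-gain
#' distributions from zero upward. When a dither frequency is given the bin
#' width defaults to `1/frequency`, so the first bin collects the short
#' events that only the dithered trap resolves.
#'
#' @param stats An [event_statistics()] object.
#' @param bin_width Bin width, s.
#' @param dither_frequency Optional dither frequency, Hz; sets
#'   `bin_width = 1/frequency` when `bin_width` is missing.
#' @param latency_gain Optional vector of bound-time gains, s.
#' @return A list of histograms (breaks, counts, mids), one per statistic.
#' @export
histogram_summaries <- function(stats, bin_width = NULL,
                                dither_frequency = NULL,
                                latency_gain = NULL) {
  if (is.null(bin_width)) {
    if (is.null(dither_frequency))
      abort_config("give bin_width or dither_frequency")
    bin_width <- 1 / dither_frequency
  }
  if (bin_width <= 0) abort_config("bin_width must be > 0")
  hist1 <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(list(breaks = numeric(0), counts = integer(0),
                                mids = numeric(0)))
    breaks <- seq(0, bin_width * ceiling(max(v, bin_width) / bin_width + 1e-9),
                  by = bin_width)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids)
  }
  out <- list(rebinding_time = hist1(stats$rebinding_times),
              bound_time = hist1(stats$bound_times))
  if (!is.null(latency_gain)) out$latency_gain <- hist1(latency_gain)
  out
}
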