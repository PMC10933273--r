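# Delimited trace I/O: tab-separated samples preceded by a '# key = value'
# header block carrying the configuration snapshot.

#' Write a force trace to a delimited text file
#'
#' Columns `time_s, force_pN, trap_pos_nm, bead_pos_nm, motor_bound`,
#' preceded by a commented `key = value` header with the configuration
#' snapshot and the ground-truth event times.
#'
#' @param trace A `force_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  cfg <- trace$config
  hdr <- c(
    sprintf("# stiffness_pN_nm = %.17g", cfg$trap$stiffness),
    sprintf("# bead_diameter_nm = %.17g", cfg$trap$bead_diameter),
    sprintf("# temperature_K = %.17g", cfg$trap$temperature),
    sprintf("# sample_rate_Hz = %.17g", cfg$trap$sample_rate),
    sprintf("# viscosity_Pa_s = %.17g", cfg$trap$viscosity),
    sprintf("# dither_enabled = %s", cfg$dither$enabled),
    sprintf("# dither_frequency_Hz = %.17g", cfg$dither$frequency),
    sprintf("# dither_peak_to_peak_nm = %.17g", cfg$dither$peak_to_peak),
    sprintf("# construct = %s", cfg$motor$construct),
    sprintf("# tether_length_nm = %.17g", cfg$motor$tether_length),
    sprintf("# d_B_MT_nm = %.17g", cfg$d_B_MT),
    sprintf("# seed = %d", cfg$seed),
    sprintf("# true_bind_times_s = %s",
            paste(sprintf("%.17g", trace$true_events$bind_time), collapse = ",")),
    sprintf("# true_unbind_times_s = %s",
            paste(sprintf("%.17g", trace$true_events$unbind_time), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\tforce_pN\ttrap_pos_nm\tbead_pos_nm\tmotor_bound", con)
  df <- as.data.frame(trace)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a force trace written by [write_trace()], or a bare table
#'
#' Also accepts bare two-column (time, force) delimited tables from real
#' instruments; missing channels are then filled with zeros and there is no
#' ground truth.
#'
#' @param path File path.
#' @return A `force_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  kv <- list()
  for (h in lines[hdr_idx]) {
    m <- regmatches(h, regexec(
      "^#[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  has_names <- grepl("time", body[1], ignore.case = TRUE)
  df <- utils::read.table(text = body, header = has_names, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_config("trace file needs at least time and force columns")
  if (ncol(df) == 2) names(df) <- c("time_s", "force_pN")
  time <- df[[1]]; force <- df[[2]]
  n <- length(time)
  sample_rate <- if (!is.null(kv$sample_rate_Hz)) as.numeric(kv$sample_rate_Hz)
                 else 1 / stats::median(diff(time))
  num <- function(key, default) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else default
  trap <- trap_config(stiffness = num("stiffness_pN_nm", 0.045),
                      bead_diameter = num("bead_diameter_nm", 560),
                      temperature = num("temperature_K", 298),
                      sample_rate = sample_rate,
                      viscosity = num("viscosity_Pa_s", 8.9e-4))
  dither <- dither_config(enabled = identical(kv$dither_enabled, "TRUE"),
                          frequency = num("dither_frequency_Hz", 20),
                          peak_to_peak = num("dither_peak_to_peak_nm", 200))
  parse_times <- function(key) {
    if (is.null(kv[[key]]) || !nzchar(kv[[key]])) return(numeric(0))
    as.numeric(strsplit(kv[[key]], ",")[[1]])
  }
  bt <- parse_times("true_bind_times_s"); ut <- parse_times("true_unbind_times_s")
  true_events <- data.frame(bind_time = bt, unbind_time = ut[seq_along(bt)],
                            truncated = rep(FALSE, length(bt)))
  bound <- if (ncol(df) >= 5) as.logical(df[[5]]) else rep(FALSE, n)
  structure(list(time = time, force = force,
                 trap_position = if (ncol(df) >= 3) df[[3]] else rep(0, n),
                 bead_position = if (ncol(df) >= 4) df[[4]] else force / trap$stiffness,
                 motor_bound = bound,
                 true_events = true_events,
                 config = list(trap = trap, dither = dither,
                               motor = motor_model(
                                 tether_length = num("tether_length_nm", 60)),
                               d_B_MT = num("d_B_MT_nm", NA_real_),
                               duration = n / sample_rate,
                               seed = as.integer(num("seed", NA)),
                               k_on = NA_real_)),
            class = "force_trace")
}
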