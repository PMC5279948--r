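#' Write a current trace to delimited text
#'
#' One file with header `time_ms,current_pA` and one row per sample, plus a
#' DCF sidecar `<path>.meta` recording carrier, capacitance, step
#' potential, step duration, sample interval and scenario label.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  df <- data.frame(time_ms = trace$time, current_pA = trace$current)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    carrier = trace$carrier,
    cm_pF = trace$cm,
    step_mV = if (!is.null(trace$protocol)) trace$protocol$step_potential[1] else NA,
    step_duration_ms = if (!is.null(trace$protocol)) trace$protocol$step_duration else NA,
    sample_interval_ms = if (!is.null(trace$protocol)) trace$protocol$sample_interval else NA,
    scenario = if (nzchar(trace$meta)) trace$meta else "unlabeled"
  )
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a current trace from delimited text
#'
#' Inverse of [write_trace_file()]; the round trip reproduces the samples
#' to full precision. Requires the header `time_ms,current_pA` and the
#' `<path>.meta` sidecar.
#'
#' @param path Trace file path.
#' @return A [current_trace()].
#' @export
read_trace_file <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  header <- readLines(path, n = 1)
  if (!identical(trimws(header), "time_ms,current_pA")) {
    stop("malformed trace file (line 1): expected header 'time_ms,current_pA'")
  }
  lines <- readLines(path)[-1]
  if (length(lines) == 0) stop("empty trace: file contains a header only")
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected 2 comma-separated fields",
                 bad[1] + 1))
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
  cur <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(tm) || anyNA(cur)) {
    bad <- which(is.na(tm) | is.na(cur))[1]
    stop(sprintf("parse error at line %d: non-numeric value", bad + 1))
  }
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
  proto <- NULL
  step_mv <- suppressWarnings(as.numeric(meta$step_mV))
  if (is.finite(step_mv)) {
    proto <- voltage_protocol(
      step_potential = step_mv,
      step_duration = as.numeric(meta$step_duration_ms),
      sample_interval = as.numeric(meta$sample_interval_ms)
    )
  }
  current_trace(tm, cur, meta$carrier, as.numeric(meta$cm_pF), proto,
                meta = if (identical(meta$scenario, "unlabeled")) "" else meta$scenario)
}

#' Write a FRET cell table
#'
#' Delimited text with header `d_free,fr` (plus `pair_label` when present).
#'
#' @param cells Data frame with columns `d_free`, `fr` and optionally
#'   `pair_label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fret_table <- function(cells, path) {
  stopifnot(all(c("d_free", "fr") %in% names(cells)))
  keep <- intersect(c("d_free", "fr", "pair_label"), names(cells))
  utils::write.csv(cells[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FRET cell table
#'
#' @param path File written by [write_fret_table()] (or any delimited text
#'   with columns `d_free`, `fr`).
#' @return A data frame.
#' @export
read_fret_table <- function(path) {
  if (!file.exists(path)) stop("FRET table not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("d_free", "fr") %in% names(df))) {
    stop("malformed FRET table: need columns d_free, fr")
  }
  df
}

#' Write a metrics table for a set of traces
#'
#' One row per trace: scenario label, step potential, carrier, peak
#' current, remaining fraction at 50 ms, CDI index and current densities.
#'
#' @param traces List of [current_trace()]s.
#' @param path Output file path (`NULL` returns the table only).
#' @return The metrics data frame, invisibly when written.
#' @export
metrics_table <- function(traces, path = NULL) {
  rows <- lapply(traces, function(tr) {
    ix <- trace_indices(tr)
    data.frame(
      scenario = if (nzchar(tr$meta)) tr$meta else "unlabeled",
      v_mV = if (!is.null(tr$protocol)) tr$protocol$step_potential[1] else NA,
      carrier = tr$carrier,
      i_peak_pA = ix$i_peak,
      r50 = ix$r_50,
      s_ca = ix$s_ca,
      j_peak_pApF = ix$j_peak,
      j300_pApF = ix$j_300
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a run configuration
#'
#' YAML with the top-level blocks `gating`, `protocol` and `schedule`;
#' every [gating_params()], [voltage_protocol()] and
#' [induction_schedule()] field can be set by name. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A list with `gating`, `protocol` and `schedule` objects (each
#'   `NULL` when the block is absent).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("gating", "protocol", "schedule")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config block(s): ", paste(extra, collapse = ", "))
  build <- function(block, fn) {
    if (is.null(block)) return(NULL)
    ok <- names(formals(fn))
    extra <- setdiff(names(block), ok)
    if (length(extra)) {
      stop("unknown key(s) in config: ", paste(extra, collapse = ", "))
    }
    do.call(fn, block)
  }
  list(
    gating = build(cfg$gating, gating_params),
    protocol = build(cfg$protocol, voltage_protocol),
    schedule = build(cfg$schedule, induction_schedule)
  )
}

#' Default run configuration as YAML text
#'
#' Every settable default, printable for `--show-config`.
#'
#' @return A YAML string.
#' @export
default_config_yaml <- function() {
  g <- unclass(gating_params())
  p <- unclass(voltage_protocol())
  s <- unclass(induction_schedule())
  yaml::as.yaml(list(gating = g, protocol = p, schedule = s))
}
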