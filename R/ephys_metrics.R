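#' Gating indices of a current trace
#'
#' Computes the standard amplitude and ratio indices from a whole-cell
#' current trace: the peak current `i_peak` (largest-magnitude sample) and
#' its time, the timed amplitudes `i_50`, `i_100`, `i_300`, `i_1000`
#' (nearest-sample lookup; `NA` when the trace is shorter), the remaining
#' fractions `r_50 = |i_50|/|i_peak|` and `r_300`, the CDI-strength index
#' `s_ca = 1 - r_50` (Ca2+ carrier only), and the capacitance-normalized
#' densities `j_peak` and `j_300` (pA/pF).
#'
#' @param trace A [current_trace()] covering at least 50 ms.
#' @return An object of class `trace_indices` (a named list).
#' @export
#' @examples
#' tr <- simulate_step_current(gating_params(), voltage_protocol())
#' idx <- trace_indices(tr)
#' c(idx$s_ca, idx$j_peak)
trace_indices <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  if (max(trace$time) < 50) stop("trace too short: must cover at least 50 ms")
  at <- function(tp) {
    if (max(trace$time) < tp) return(NA_real_)
    trace$current[which.min(abs(trace$time - tp))]
  }
  k <- which.max(abs(trace$current))
  i_peak <- trace$current[k]
  if (abs(i_peak) == 0) stop("flat zero trace: peak amplitude is zero")
  i_50 <- at(50); i_100 <- at(100); i_300 <- at(300); i_1000 <- at(1000)
  r_50 <- abs(i_50) / abs(i_peak)
  r_300 <- if (is.na(i_300)) NA_real_ else abs(i_300) / abs(i_peak)
  structure(
    list(
      i_peak = i_peak, t_peak = trace$time[k],
      i_50 = i_50, i_100 = i_100, i_300 = i_300, i_1000 = i_1000,
      r_50 = r_50, r_300 = r_300,
      s_ca = if (trace$carrier == "Ca") 1 - r_50 else NA_real_,
      j_peak = i_peak / trace$cm,
      j_300 = if (is.na(i_300)) NA_real_ else i_300 / trace$cm,
      carrier = trace$carrier, cm = trace$cm
    ),
    class = "trace_indices"
  )
}

#' @export
print.trace_indices <- function(x, ...) {
  cat(sprintf(
    "<trace_indices> %s: i_peak=%.3g pA (t=%.3g ms), r_50=%.4f, r_300=%s, s_ca=%s, j_peak=%.3g pA/pF\n",
    x$carrier, x$i_peak, x$t_peak, x$r_50,
    ifelse(is.na(x$r_300), "NA", sprintf("%.4f", x$r_300)),
    ifelse(is.na(x$s_ca), "NA", sprintf("%.4f", x$s_ca)), x$j_peak))
  invisible(x)
}

step_voltages <- function(traces) {
  vapply(traces, function(tr) {
    if (is.null(tr$protocol)) stop("trace lacks protocol metadata")
    tr$protocol$step_potential[1]
  }, numeric(1))
}

#' Inactivation profile across a voltage family
#'
#' The remaining fraction at 50 ms for Ca2+ and Ba2+ families sharing the
#' same voltage grid, the pure-CDI difference `r50_ba - r50_ca`, and the
#' simplified CDI-strength index `s_ca_at_minus10 = 1 - r50_ca(-10 mV)`,
#' the single-number index used throughout for CDI strength.
#'
#' @param traces_ca List of Ca2+ [current_trace()]s (one per voltage).
#' @param traces_ba List of Ba2+ traces on the same voltage grid.
#' @return A list with `voltages`, `r50_ca`, `r50_ba`, `cdi_diff` and
#'   `s_ca_at_minus10`.
#' @export
cdi_profile <- function(traces_ca, traces_ba) {
  v_ca <- step_voltages(traces_ca)
  v_ba <- step_voltages(traces_ba)
  if (length(v_ca) != length(v_ba) || any(v_ca != v_ba)) {
    stop("Ca and Ba families must share the same voltage grid")
  }
  r50_ca <- vapply(traces_ca, function(tr) trace_indices(tr)$r_50, numeric(1))
  r50_ba <- vapply(traces_ba, function(tr) trace_indices(tr)$r_50, numeric(1))
  i10 <- which(v_ca == -10)
  list(
    voltages = v_ca, r50_ca = r50_ca, r50_ba = r50_ba,
    cdi_diff = r50_ba - r50_ca,
    s_ca_at_minus10 = if (length(i10)) 1 - r50_ca[i10] else NA_real_
  )
}

#' Current-density (voltage-gated activation) profile
#'
#' Peak and 300-ms current densities across a Ca2+ step family, plus the
#' single-number activation index `j_ca_at_minus10` (peak density at
#' -10 mV).
#'
#' @param traces_ca List of Ca2+ [current_trace()]s (one per voltage).
#' @param cm Membrane capacitance (pF); defaults to the traces' own.
#' @return A list with `voltages`, `j_peak`, `j_300` and `j_ca_at_minus10`.
#' @export
vga_profile <- function(traces_ca, cm = NULL) {
  v <- step_voltages(traces_ca)
  idx <- lapply(traces_ca, trace_indices)
  jp <- vapply(seq_along(idx), function(i) {
    cmi <- if (is.null(cm)) traces_ca[[i]]$cm else cm
    if (cmi <= 0) stop("cm must be positive")
    idx[[i]]$i_peak / cmi
  }, numeric(1))
  j3 <- vapply(seq_along(idx), function(i) {
    cmi <- if (is.null(cm)) traces_ca[[i]]$cm else cm
    idx[[i]]$i_300 / cmi
  }, numeric(1))
  i10 <- which(v == -10)
  list(voltages = v, j_peak = jp, j_300 = j3,
       j_ca_at_minus10 = if (length(i10)) jp[i10] else NA_real_)
}

#' Summarize a sweep time course
#'
#' Per-sweep table of the CDI index and peak/late amplitudes normalized to
#' sweep 1, as plotted for drug-induction and run-down experiments.
#'
#' @param sweeps List of at least two [current_trace()]s; sweep times (s)
#'   are taken from the `sweep_times` attribute when present, else from
#'   the repetition interval.
#' @return A data frame with columns `time_s`, `s_ca`, `i_peak_norm`,
#'   `i_300_norm`.
#' @export
timecourse_summary <- function(sweeps) {
  if (length(sweeps) < 2) stop("need at least 2 sweeps")
  times <- attr(sweeps, "sweep_times")
  if (is.null(times)) {
    rep_int <- sweeps[[1]]$protocol$repetition_interval
    if (is.null(rep_int)) rep_int <- 30
    times <- (seq_along(sweeps) - 1) * rep_int
  }
  idx <- lapply(sweeps, trace_indices)
  peak1 <- abs(idx[[1]]$i_peak)
  i300_1 <- abs(idx[[1]]$i_300)
  data.frame(
    time_s = times,
    s_ca = vapply(idx, `[[`, numeric(1), "s_ca"),
    i_peak_norm = vapply(idx, function(x) abs(x$i_peak) / peak1, numeric(1)),
    i_300_norm = vapply(idx, function(x) abs(x$i_300) / i300_1, numeric(1))
  )
}

#' Classify the modality of an inhibition
#'
#' Decision rule distinguishing C-terminus-mediated inhibition from
#' conventional inhibitions (blockage, run-down): CMI drops the peak and
#' the CDI index but keeps the 300-ms amplitude constant; conventional
#' inhibition drops peak and 300-ms amplitude together with the CDI index
#' unaltered. A change is "significant" when the relative drop exceeds
#' `tol_rel`.
#'
#' @param baseline [trace_indices()] of the reference condition.
#' @param test [trace_indices()] of the test condition (same protocol and
#'   carrier).
#' @param tol_rel Relative-change threshold (default 0.10).
#' @return One of `"cmi"`, `"conventional"`, `"mixed"`, `"none"`.
#' @export
classify_inhibition <- function(baseline, test, tol_rel = 0.10) {
  stopifnot(inherits(baseline, "trace_indices"), inherits(test, "trace_indices"))
  if (baseline$carrier != test$carrier) {
    stop("baseline and test must share the same carrier")
  }
  rel_drop <- function(b, t) (abs(b) - abs(t)) / abs(b)
  d_peak <- rel_drop(baseline$i_peak, test$i_peak) > tol_rel
  d_i300 <- rel_drop(baseline$i_300, test$i_300) > tol_rel
  d_s <- (baseline$s_ca - test$s_ca) / baseline$s_ca > tol_rel
  if (d_peak && d_s && !d_i300) return("cmi")
  if (d_peak && d_i300 && !d_s) return("conventional")
  if (!d_peak && !d_i300 && !d_s) return("none")
  "mixed"
}
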