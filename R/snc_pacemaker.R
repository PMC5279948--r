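#' Parameters of the minimal SNc pacemaker neuron
#'
#' A single-compartment conductance-based model of a substantia nigra pars
#' compacta dopaminergic neuron: Hodgkin-Huxley-style Na+ and K+ spiking
#' currents, an ohmic leak with a depolarized reversal (the background
#' pacemaker drive), and the CaV1.3 L-type Ca2+ current whose CDI is
#' driven by submembrane Ca2+. CMI is the two-population weighting: a
#' fraction `w` of the CaV1.3 conductance is pinned at the end-stage
#' availability `r_inf_max` (no CDI), the rest carries Ca2+-dependent
#' inactivation — the dynamic counterpart of the constant-I300 rule.
#'
#' Defaults were tuned once to autonomous pacemaking in the 1-4 Hz range
#' typical of SNc dopaminergic neurons, then frozen.
#'
#' @param capacitance Membrane capacitance (pF).
#' @param g_na,e_na Na+ maximal conductance (nS) and reversal (mV);
#'   `mode = "oscillation"` forces `g_na = 0` (TTX-like).
#' @param v_shift_na Rightward voltage shift of the Na+ gating functions
#'   (mV), placing spike threshold above the subthreshold Ca2+ wave's
#'   trough so that spikes ride the wave's crests instead of firing
#'   tonically.
#' @param g_k,e_k Delayed-rectifier K+ conductance (nS) and reversal (mV).
#' @param g_leak,e_leak Leak conductance (nS) and reversal (mV); the
#'   depolarized leak reversal is the background pacemaker drive.
#' @param g_sk,k_sk Small-conductance Ca2+-activated K+ (SK) maximal
#'   conductance (nS) and half-activation Ca2+ concentration (uM);
#'   instantaneous Hill-4 activation, reversal at `e_k`.
#' @param g_cal,e_ca CaV1.3 maximal conductance (nS) and Ca2+ reversal (mV).
#' @param vh_ca,k_ca CaL activation midpoint and slope (mV); CaV1.3
#'   activates subthreshold in neurons.
#' @param kappa Influx-to-concentration factor (uM per pA*ms).
#' @param tau_ca Submembrane Ca2+ extrusion time constant (ms).
#' @param k_cdi Half-inactivation Ca2+ concentration (uM).
#' @param hill_n Hill exponent of Ca2+-dependent inactivation.
#' @param tau_h CDI onset time constant (ms).
#' @param tau_h_rec CDI recovery-from-inactivation time constant (ms);
#'   recovery is much slower than onset, as for CaV1 CDI.
#' @param r_inf_max End-stage remaining fraction (CDI floor).
#' @param w CMI weight in \[0, 1\].
#' @param block_fraction Conventional-block fraction on `g_cal`, \[0, 1).
#' @param mode `"pacemaking"` (full model) or `"oscillation"`
#'   (`g_na = 0`, subthreshold Ca2+ oscillation).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(capacitance = 30,
                          g_na = 700, e_na = 50, v_shift_na = 22,
                          g_k = 210, e_k = -90,
                          g_leak = 2.4, e_leak = -59,
                          g_sk = 0, k_sk = 0.5,
                          g_cal = 21, e_ca = 45,
                          vh_ca = -40, k_ca = 3.4,
                          kappa = 4.4e-4, tau_ca = 40,
                          k_cdi = 0.58, hill_n = 4, tau_h = 35,
                          tau_h_rec = 1200,
                          r_inf_max = 0.20, w = 0,
                          block_fraction = 0,
                          mode = c("pacemaking", "oscillation")) {
  mode <- match.arg(mode)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (block_fraction < 0 || block_fraction >= 1) {
    stop("block_fraction must lie in [0, 1)")
  }
  if (any(c(g_na, g_k, g_leak, g_sk, g_cal) < 0)) stop("conductances must be >= 0")
  if (tau_h_rec < tau_h) stop("tau_h_rec must be >= tau_h (recovery slower than onset)")
  if (mode == "oscillation") g_na <- 0
  structure(
    list(capacitance = capacitance, g_na = g_na, e_na = e_na,
         v_shift_na = v_shift_na,
         g_k = g_k, e_k = e_k, g_leak = g_leak, e_leak = e_leak,
         g_sk = g_sk, k_sk = k_sk,
         g_cal = g_cal, e_ca = e_ca, vh_ca = vh_ca, k_ca = k_ca,
         kappa = kappa, tau_ca = tau_ca, k_cdi = k_cdi, hill_n = hill_n,
         tau_h = tau_h, tau_h_rec = tau_h_rec, r_inf_max = r_inf_max, w = w,
         block_fraction = block_fraction, mode = mode),
    class = "neuron_params"
  )
}

#' Simulate the SNc pacemaker model
#'
#' Integrates the neuron ODE system with fixed-step RK4 (deterministic for
#' fixed inputs), detects events with [measure_rate()] and summarizes the
#' CaV1.3-mediated Ca2+ influx.
#'
#' @param params A [neuron_params()] object.
#' @param duration Simulated time (ms); >= 5000 ms recommended for rate
#'   estimation.
#' @param dt Integration step (ms), <= 0.05.
#' @param record_dt Recording interval (ms) for the stored traces.
#' @param settle Initial transient (ms) excluded from event detection and
#'   influx summaries (the full record is still returned).
#' @return An object of class `pacemaker_result`: `time`, `v`, `ca_sub`,
#'   `i_cal` (all arrays), `spike_times` (ms), `rate` (Hz),
#'   `ca_influx_per_s` (pC/s), `quiescent` flag and `mode`.
#' @export
#' @examples
#' \donttest{
#' res <- simulate_pacemaker(neuron_params(), duration = 10000)
#' res$rate
#' }
simulate_pacemaker <- function(params, duration = 20000, dt = 0.025,
                               record_dt = 0.1, settle = 1000) {
  stopifnot(inherits(params, "neuron_params"))
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  if (duration < 1000 + settle) stop("duration too short for meaningful analysis")
  raw <- .pacemaker_rk4(unclass(params), duration, dt, record_dt)
  res <- structure(
    list(time = raw$time, v = raw$v, ca_sub = raw$ca_sub, i_cal = raw$i_cal,
         spike_times = numeric(0), rate = 0, ca_influx_per_s = NA_real_,
         quiescent = TRUE, mode = params$mode, settle = settle),
    class = "pacemaker_result"
  )
  keep <- raw$time >= settle
  rr <- measure_rate(list(time = raw$time[keep], v = raw$v[keep]), params$mode)
  res$spike_times <- attr(rr, "event_times")
  res$rate <- as.numeric(rr)
  res$quiescent <- isTRUE(attr(rr, "quiescent"))
  res$ca_influx_per_s <- ca_influx(res, window = c(settle, max(raw$time)))
  res
}

#' @export
print.pacemaker_result <- function(x, ...) {
  cat(sprintf(
    "<pacemaker_result> %s: %.3g s simulated, %d events, rate %.3g Hz, Ca2+ influx %.3g pC/s%s\n",
    x$mode, max(x$time) / 1000, length(x$spike_times), x$rate,
    x$ca_influx_per_s, if (x$quiescent) " [quiescent]" else ""))
  invisible(x)
}

#' Event rate of a simulated voltage trace
#'
#' Pacemaking mode counts upward crossings of 0 mV with a 2-ms refractory;
#' oscillation mode counts upward crossings of the trace's mean level with
#' a 50-ms refractory. The rate is `(n_events - 1) / span` (Hz) for two or
#' more events, else 0 with a quiescence flag.
#'
#' @param result A [simulate_pacemaker()] result (or any list with `time`
#'   in ms and `v` in mV).
#' @param mode `"pacemaking"` or `"oscillation"`.
#' @return Rate in Hz, with attributes `event_times` (ms) and `quiescent`.
#' @export
measure_rate <- function(result, mode = c("pacemaking", "oscillation")) {
  mode <- match.arg(mode)
  t <- result$time; v <- result$v
  if (mode == "pacemaking") {
    threshold <- 0; refractory <- 2
  } else {
    threshold <- mean(v); refractory <- 50
  }
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  events <- numeric(0)
  last <- -Inf
  for (k in up) {
    if (t[k] - last >= refractory) {
      events <- c(events, t[k]); last <- t[k]
    }
  }
  if (length(events) < 2) {
    return(structure(0, event_times = events, quiescent = TRUE))
  }
  rate <- (length(events) - 1) / (events[length(events)] - events[1]) * 1000
  structure(rate, event_times = events, quiescent = FALSE)
}

#' Mean CaV1.3 Ca2+ influx
#'
#' Time integral of the L-type Ca2+ current magnitude over a window,
#' divided by the window length: `pA * ms / ms = pA`, i.e. pC/s.
#'
#' @param result A [simulate_pacemaker()] result.
#' @param window Length-2 window (ms) within the simulated span; default
#'   the full record.
#' @return Mean influx in pC/s.
#' @export
ca_influx <- function(result, window = NULL) {
  t <- result$time; i <- abs(result$i_cal)
  if (is.null(window)) window <- range(t)
  if (window[1] < min(t) || window[2] > max(t) || window[2] <= window[1]) {
    stop("window must lie within the simulated span")
  }
  sel <- t >= window[1] & t <= window[2]
  ts <- t[sel]; is <- i[sel]
  # trapezoidal integral / window length
  sum(diff(ts) * (is[-1] + is[-length(is)]) / 2) / (ts[length(ts)] - ts[1])
}

#' Sweep the CMI weight
#'
#' Runs [simulate_pacemaker()] at each CMI weight and tabulates rate and
#' Ca2+ influx; both are non-increasing in `w` (within rate-estimation
#' granularity).
#'
#' @param params A [neuron_params()] object (its `w` is overridden).
#' @param w_values CMI weights in \[0, 1\].
#' @param duration,dt Passed to [simulate_pacemaker()].
#' @return A data frame with columns `w`, `rate`, `influx`.
#' @export
sweep_cmi <- function(params, w_values = c(0, 0.25, 0.5, 0.75, 1),
                      duration = 20000, dt = 0.025) {
  stopifnot(all(w_values >= 0 & w_values <= 1))
  rows <- lapply(w_values, function(wv) {
    p <- params; p$w <- wv
    res <- simulate_pacemaker(p, duration, dt)
    data.frame(w = wv, rate = res$rate, influx = res$ca_influx_per_s)
  })
  do.call(rbind, rows)
}

#' Voltage-clamp harness for the dynamic CaV1.3 mechanism
#'
#' Clamps the membrane potential to a step while the CDI gate and
#' submembrane Ca2+ evolve, returning the resulting L-type Ca2+ current as
#' a [current_trace()] so that [trace_indices()] applies. This is the
#' dynamic analogue of the trace-level model: S_Ca decreases with `w` and
#' the late-phase current is insensitive to `w`.
#'
#' @param params A [neuron_params()] object.
#' @param v_step Clamp potential (mV), default -10.
#' @param duration Step duration (ms), default 300.
#' @param dt Integration step (ms).
#' @param record_dt Sample interval of the returned trace (ms).
#' @return A [current_trace()] with carrier `"Ca"`.
#' @export
cal_clamp_trace <- function(params, v_step = -10, duration = 300,
                            dt = 0.025, record_dt = 0.5) {
  stopifnot(inherits(params, "neuron_params"))
  raw <- .cal_clamp_rk4(unclass(params), v_step, duration, dt, record_dt)
  current_trace(raw$time, raw$i_cal, "Ca", params$capacitance,
                voltage_protocol(step_potential = v_step,
                                 step_duration = duration,
                                 sample_interval = record_dt),
                meta = sprintf("clamp w=%g block=%g", params$w,
                               params$block_fraction))
}
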