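#' Voltage-step protocol
#'
#' Describes a whole-cell voltage-clamp step protocol: a holding potential,
#' one step potential (or a family of them), the step duration, the sampling
#' interval and the repetition interval between sweeps.
#'
#' @param holding_potential Holding potential (mV). Default -70 mV.
#' @param step_potential Step potential(s) (mV). A scalar for a single step
#'   or a vector for a step family. Default -10 mV.
#' @param step_duration Step duration (ms). Default 300 ms.
#' @param sample_interval Sampling interval (ms). Must not exceed
#'   `step_duration / 100`. Default 0.5 ms.
#' @param repetition_interval Interval between successive sweeps (s).
#'   Default 30 s.
#' @return An object of class `voltage_protocol`.
#' @export
#' @examples
#' voltage_protocol()                       # single -10 mV, 300 ms step
#' voltage_protocol(step_potential = seq(-70, 50, by = 10))
voltage_protocol <- function(holding_potential = -70,
                             step_potential = -10,
                             step_duration = 300,
                             sample_interval = 0.5,
                             repetition_interval = 30) {
  stopifnot(is.numeric(step_potential), length(step_potential) >= 1)
  if (step_duration <= 0) stop("step_duration must be positive")
  if (sample_interval <= 0) stop("sample_interval must be positive")
  if (sample_interval > step_duration / 100) {
    stop("sample_interval must be <= step_duration/100 (need >= 100 samples per step)")
  }
  structure(
    list(
      holding_potential = holding_potential,
      step_potential = as.numeric(step_potential),
      step_duration = step_duration,
      sample_interval = sample_interval,
      repetition_interval = repetition_interval
    ),
    class = "voltage_protocol"
  )
}

#' Default step family spanning -70 to +50 mV in 10-mV increments
#'
#' The canonical step family used for current-voltage and inactivation
#' profiles, and as the normalization grid for the voltage dependence of the
#' CDI floor.
#'
#' @return Numeric vector of step potentials (mV).
#' @export
default_step_family <- function() seq(-70, 50, by = 10)

#' CaV1.3 gating parameters
#'
#' Parameters of the phenomenological whole-cell CaV1.3 current model:
#' Boltzmann activation, single-exponential CDI to a voltage-scaled floor,
#' slow exponential voltage-dependent inactivation (VDI, the only
#' inactivation with Ba2+ as charge carrier), and the CMI mixture weight
#' `w`. `w = 0` is the uninhibited channel, `w = 1` the ultrastrong-CMI
#' limit in which the current is pinned at the end-stage CDI amplitude.
#'
#' The default conductance density is chosen so the peak Ca2+ current
#' density at -10 mV is -20 pA/pF; `tau_cdi` and `r_inf_max` are the
#' calibration that reproduces the measured index triple
#' (S_Ca baseline 0.77, peak fraction 0.35, S_Ca under CMI 0.41), see
#' [calibrate_cdi_params()].
#'
#' @param v_half Activation midpoint (mV).
#' @param k_slope Activation slope factor (mV); must be nonzero.
#' @param e_rev Reversal potential (mV).
#' @param g_density Maximal conductance per capacitance (nS/pF). `NULL`
#'   (default) picks the value giving a -20 pA/pF peak density at -10 mV.
#' @param tau_act Activation time constant (ms); 0 means instantaneous.
#' @param tau_cdi CDI time constant (ms).
#' @param r_inf_max End-stage remaining fraction at the voltage of maximal
#'   Ca2+ current, in (0, 1).
#' @param tau_vdi VDI time constant (ms); governs Ba2+ inactivation
#'   (default 1640 ms gives r_50,Ba of about 0.97).
#' @param w CMI mixture weight in \[0, 1\].
#' @return An object of class `gating_params`.
#' @export
#' @examples
#' gating_params()               # baseline, no CMI
#' gating_params(w = 0.8125)     # the inducible-CMI scenario weight
gating_params <- function(v_half = -20, k_slope = 7, e_rev = 45,
                          g_density = NULL, tau_act = 0,
                          tau_cdi = 15, r_inf_max = 0.20,
                          tau_vdi = 1640, w = 0) {
  if (k_slope == 0) stop("k_slope must be nonzero")
  if (!(r_inf_max > 0 && r_inf_max < 1)) stop("r_inf_max must lie in (0, 1)")
  if (tau_cdi <= 0) stop("tau_cdi must be positive")
  if (tau_vdi <= tau_cdi) stop("tau_vdi must exceed tau_cdi (VDI is much slower than CDI)")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (tau_act < 0) stop("tau_act must be >= 0")
  p <- list(
    v_half = v_half, k_slope = k_slope, e_rev = e_rev,
    g_density = 1, tau_act = tau_act, tau_cdi = tau_cdi,
    r_inf_max = r_inf_max, tau_vdi = tau_vdi, w = w
  )
  if (is.null(g_density)) {
    # scale so peak Ca2+ current density at -10 mV is -20 pA/pF
    g_density <- -20 / drive_density(-10, p)
  }
  if (g_density <= 0) stop("g_density must be positive")
  p$g_density <- g_density
  structure(p, class = "gating_params")
}

#' Boltzmann activation curve
#'
#' Steady-state activation `m_inf(V) = 1 / (1 + exp(-(V - v_half)/k_slope))`.
#'
#' @param v Membrane potential(s) (mV).
#' @param params A [gating_params()] object.
#' @return Open fraction in \[0, 1\], monotone increasing in `v`.
#' @export
activation_curve <- function(v, params) {
  stopifnot(inherits(params, "gating_params"))
  1 / (1 + exp(-(v - params$v_half) / params$k_slope))
}

# signed driving amplitude per unit g_density: (V - E_rev) * m_inf(V), pA/pF
# for g_density = 1 nS/pF; inward currents come out negative.
drive_density <- function(v, params) {
  (v - params$e_rev) / (1 + exp(-(v - params$v_half) / params$k_slope))
}

#' Voltage-dependent CDI floor
#'
#' The end-stage remaining fraction `r_inf(V)` of the CDI gate. CDI depth
#' scales with the peak Ca2+ current magnitude at each voltage, normalized
#' to its maximum over the step family, so the CDI strength profile is
#' U-shaped and mirrors the V-shaped current-density profile:
#' `1 - r_inf(V) = (1 - r_inf_max) * u(V)` with `u` the normalized current
#' magnitude.
#'
#' @param v Step potential(s) (mV).
#' @param params A [gating_params()] object.
#' @param family_v Voltage grid over which the current magnitude is
#'   normalized; defaults to [default_step_family()].
#' @return Remaining fraction(s) in (0, 1].
#' @export
cdi_floor <- function(v, params, family_v = default_step_family()) {
  stopifnot(inherits(params, "gating_params"))
  u_max <- max(abs(drive_density(family_v, params)))
  u <- abs(drive_density(v, params)) / u_max
  1 - (1 - params$r_inf_max) * u
}

#' CDI gate time course
#'
#' Remaining CDI-gate fraction at time `t` after step onset:
#' `h_Ca(t, V) = r_inf(V) + (1 - r_inf(V)) * exp(-t / tau_cdi)`, with the
#' voltage-scaled floor from [cdi_floor()]. `h(0) = 1`; the steady state at
#' the voltage of maximal current is `r_inf_max`.
#'
#' @param t Time(s) since step onset (ms), `t >= 0`.
#' @param v Step potential (mV).
#' @param params A [gating_params()] object.
#' @param family_v Normalization grid passed to [cdi_floor()].
#' @return Gate fraction(s) in (0, 1].
#' @export
cdi_gate <- function(t, v, params, family_v = default_step_family()) {
  if (any(t < 0)) stop("t must be >= 0")
  r_inf <- cdi_floor(v, params, family_v)
  r_inf + (1 - r_inf) * exp(-t / params$tau_cdi)
}

#' Construct a current trace object
#'
#' @param time Sample times (ms), strictly increasing from 0 (step onset).
#' @param current Current samples (pA, inward negative); same length as
#'   `time`.
#' @param carrier Charge carrier, `"Ca"` or `"Ba"`.
#' @param cm Membrane capacitance (pF).
#' @param protocol The [voltage_protocol()] used (single step).
#' @param meta Optional scenario label.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time, current, carrier = c("Ca", "Ba"), cm,
                          protocol = NULL, meta = "") {
  carrier <- match.arg(carrier)
  if (length(time) != length(current)) {
    stop("time and current must have the same length")
  }
  if (length(time) == 0) stop("empty trace")
  if (time[1] != 0 || any(diff(time) <= 0)) {
    stop("time must be strictly increasing and start at 0")
  }
  if (cm <= 0) stop("cm must be positive")
  structure(
    list(time = as.numeric(time), current = as.numeric(current),
         carrier = carrier, cm = cm, protocol = protocol, meta = meta),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  v <- if (!is.null(x$protocol)) x$protocol$step_potential[1] else NA
  cat(sprintf(
    "<current_trace> %s, %g pF, step %s mV, %d samples over %g ms%s\n",
    x$carrier, x$cm, format(v), length(x$time), max(x$time),
    if (nzchar(x$meta)) paste0(" [", x$meta, "]") else ""
  ))
  invisible(x)
}

#' Simulate a whole-cell current under a voltage step
#'
#' Generates the model current for one step potential. With Ca2+ as charge
#' carrier the current is the CMI mixture of a CDI-capable state and a
#' non-inactivating state pinned at the end-stage amplitude:
#' \deqn{I(t) = c_m\, g\, (V - E_{rev})\, m_\infty(V)\, m(t)\,
#'       [(1-w)\, h_{Ca}(t,V) + w\, r_{300}(V)]}
#' where the pinned level `r_300(V) = h_Ca(300 ms, V)` is the CDI
#' amplitude at the end-stage time point (300 ms, numerically
#' indistinguishable from the asymptotic floor `r_inf(V)` at the default
#' `tau_cdi`), so the current at 300 ms is exactly invariant in `w` (the
#' constant-I300 rule).
#' With Ba2+ there is no CDI and the trace decays only by slow VDI:
#' `I(t) = A(V) m(t) exp(-t/tau_vdi)`. Slow VDI is carrier-independent in
#' origin but, over a 300-ms Ca2+ step, is absorbed into the calibrated CDI
#' floor rather than applied as a second multiplicative factor (it is only
#' a few percent at 50 ms and would otherwise be double-counted by the
#' calibration); it is modeled explicitly where it is the sole
#' inactivation, i.e. for Ba2+.
#'
#' @param params A [gating_params()] object.
#' @param protocol A [voltage_protocol()] with a single step potential.
#' @param carrier `"Ca"` or `"Ba"`.
#' @param cm Membrane capacitance (pF), positive.
#' @param family_v Normalization grid for the CDI floor; defaults to the
#'   protocol's own family when it has several steps, else
#'   [default_step_family()].
#' @param meta Optional scenario label stored on the trace.
#' @return A [current_trace()].
#' @export
#' @examples
#' tr <- simulate_step_current(gating_params(), voltage_protocol())
#' trace_indices(tr)$s_ca   # 0.77 at the frozen defaults
simulate_step_current <- function(params, protocol = voltage_protocol(),
                                  carrier = c("Ca", "Ba"), cm = 10,
                                  family_v = NULL, meta = "") {
  carrier <- match.arg(carrier)
  stopifnot(inherits(params, "gating_params"),
            inherits(protocol, "voltage_protocol"))
  if (length(protocol$step_potential) != 1) {
    stop("protocol must have a single step potential; use simulate_step_family() for families")
  }
  if (cm <= 0) stop("cm must be positive")
  if (params$w < 0 || params$w > 1) stop("w must lie in [0, 1]")
  if (is.null(family_v)) family_v <- default_step_family()

  v <- protocol$step_potential
  t <- seq(0, protocol$step_duration, by = protocol$sample_interval)
  m_t <- if (params$tau_act > 0) 1 - exp(-t / params$tau_act) else rep(1, length(t))
  amp <- cm * params$g_density * drive_density(v, params)
  inact <- if (carrier == "Ca") {
    r_inf <- cdi_floor(v, params, family_v)
    h <- r_inf + (1 - r_inf) * exp(-t / params$tau_cdi)
    # CMI component pinned at the end-stage (300-ms) CDI amplitude, so
    # I(300 ms) is exactly w-invariant
    r_pin <- r_inf + (1 - r_inf) * exp(-300 / params$tau_cdi)
    (1 - params$w) * h + params$w * r_pin
  } else {
    exp(-t / params$tau_vdi)
  }
  current_trace(t, amp * m_t * inact, carrier, cm, protocol, meta)
}

#' Simulate a family of step currents
#'
#' Runs [simulate_step_current()] for every step potential in the protocol,
#' normalizing the CDI floor over the family itself.
#'
#' @inheritParams simulate_step_current
#' @return A list of [current_trace()] objects, one per step potential.
#' @export
simulate_step_family <- function(params,
                                 protocol = voltage_protocol(
                                   step_potential = default_step_family()),
                                 carrier = c("Ca", "Ba"), cm = 10, meta = "") {
  carrier <- match.arg(carrier)
  family_v <- protocol$step_potential
  lapply(family_v, function(v) {
    p1 <- protocol
    p1$step_potential <- v
    simulate_step_current(params, p1, carrier, cm, family_v = family_v,
                          meta = meta)
  })
}

#' Mixture weight producing a given peak-current fraction
#'
#' Inverts the peak-reduction relation of the CMI mixture under
#' instantaneous activation: a weight `w` leaves a fraction
#' `1 - w (1 - r_inf)` of the baseline peak, so
#' `w = (1 - f_remaining) / (1 - r_inf)`. A mixture cannot push the peak
#' below the end-stage floor `r_inf`.
#'
#' @param f_remaining Target remaining peak fraction, `r_inf < f <= 1`.
#' @param r_inf End-stage remaining fraction at the test voltage.
#' @return The mixture weight `w` in \[0, 1\].
#' @export
#' @examples
#' mixture_weight_for_peak_fraction(0.35, 0.20)   # 0.8125
mixture_weight_for_peak_fraction <- function(f_remaining, r_inf) {
  if (!(r_inf > 0 && r_inf < 1)) stop("r_inf must lie in (0, 1)")
  if (f_remaining > 1) stop("f_remaining cannot exceed 1")
  if (f_remaining < r_inf) {
    stop(sprintf(
      "infeasible: requested peak fraction %.3g is below the end-stage floor %.3g (the lower limit of CMI)",
      f_remaining, r_inf))
  }
  (1 - f_remaining) / (1 - r_inf)
}

#' Calibrate CDI/CMI parameters from the measured index triple
#'
#' Solves the consistency system linking the baseline CDI index, the
#' CMI peak fraction and the CMI CDI index to the model parameters
#' (instantaneous activation assumed):
#' \itemize{
#'   \item `r50 = 1 - s_ca_baseline`
#'   \item `peak_fraction = 1 - w (1 - r_inf)`
#'   \item `(w r_inf + (1 - w) r50) / peak_fraction = 1 - s_ca_cmi`
#'   \item `r50 = r_inf + (1 - r_inf) exp(-50 / tau_cdi)`
#' }
#' The system is exactly determined; the solution is
#' `w = 1 - peak_fraction * s_ca_cmi / s_ca_baseline`,
#' `r_inf = 1 - (1 - peak_fraction)/w`, and `tau_cdi` from the last
#' equation. Infeasible triples (no admissible `(w, r_inf, tau_cdi)`) are
#' rejected.
#'
#' @param s_ca_baseline Baseline CDI index, in (0, 1).
#' @param peak_fraction_cmi Remaining peak fraction under CMI, in (0, 1).
#' @param s_ca_cmi CDI index under CMI; must be below `s_ca_baseline`.
#' @return A list with `tau_cdi` (ms), `r_inf_max` and `w`.
#' @export
#' @examples
#' calibrate_cdi_params(0.77, 0.35, 0.41)
calibrate_cdi_params <- function(s_ca_baseline, peak_fraction_cmi, s_ca_cmi) {
  if (!(s_ca_cmi > 0 && s_ca_cmi < s_ca_baseline && s_ca_baseline < 1)) {
    stop("need 0 < s_ca_cmi < s_ca_baseline < 1")
  }
  if (!(peak_fraction_cmi > 0 && peak_fraction_cmi < 1)) {
    stop("peak_fraction_cmi must lie in (0, 1)")
  }
  r50 <- 1 - s_ca_baseline
  w <- 1 - peak_fraction_cmi * s_ca_cmi / s_ca_baseline
  if (w <= 0 || w > 1) {
    stop("infeasible: implied mixture weight outside (0, 1]")
  }
  r_inf <- 1 - (1 - peak_fraction_cmi) / w
  if (r_inf <= 0) {
    stop("infeasible: implied end-stage floor is nonpositive")
  }
  if (r_inf >= r50) {
    stop(sprintf(
      "infeasible: implied end-stage floor %.3g is not below r50 = %.3g",
      r_inf, r50))
  }
  tau_cdi <- -50 / log((r50 - r_inf) / (1 - r_inf))
  list(tau_cdi = tau_cdi, r_inf_max = r_inf, w = w)
}

#' Scale conductance by a conventional block
#'
#' Models pore blockage (or any loss of functional channels) by scaling the
#' conductance density by `1 - block_fraction`, leaving all gating kinetics
#' untouched; S_Ca of the resulting trace is unchanged and I_peak and I_300
#' scale identically.
#'
#' @param params A [gating_params()] object.
#' @param block_fraction Fraction of conductance removed, in \[0, 1).
#' @return A modified [gating_params()] object.
#' @export
apply_block <- function(params, block_fraction) {
  stopifnot(inherits(params, "gating_params"))
  if (block_fraction < 0 || block_fraction >= 1) {
    stop("block_fraction must lie in [0, 1)")
  }
  params$g_density <- params$g_density * (1 - block_fraction)
  params
}

#' Drug-induction schedule
#'
#' Saturating-exponential (perfusion-limited) time course of the CMI
#' weight: `w(t) = w_final * (1 - exp(-max(t - t_onset, 0)/tau_perfusion))`,
#' non-decreasing and bounded by `w_final`. With the default
#' `tau_perfusion = 75` s, w reaches at least 97% of plateau by 4-5 min.
#'
#' @param t_onset Drug-application onset (s).
#' @param tau_perfusion Perfusion time constant (s).
#' @param w_final Plateau CMI weight in \[0, 1\].
#' @param n_sweeps Number of sweeps recorded.
#' @param sweep_interval Interval between sweeps (s).
#' @return An object of class `induction_schedule`.
#' @export
induction_schedule <- function(t_onset = 60, tau_perfusion = 75,
                               w_final = 0.8125, n_sweeps = 21,
                               sweep_interval = 30) {
  if (tau_perfusion <= 0) stop("tau_perfusion must be positive")
  if (w_final < 0 || w_final > 1) stop("w_final must lie in [0, 1]")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (sweep_interval <= 0) stop("sweep_interval must be positive")
  structure(
    list(t_onset = t_onset, tau_perfusion = tau_perfusion,
         w_final = w_final, n_sweeps = n_sweeps,
         sweep_interval = sweep_interval),
    class = "induction_schedule"
  )
}

#' CMI weight at a given time under an induction schedule
#'
#' @param t Time(s) since recording start (s).
#' @param schedule An [induction_schedule()].
#' @return w(t), non-decreasing, bounded by `w_final`.
#' @export
induction_weight <- function(t, schedule) {
  stopifnot(inherits(schedule, "induction_schedule"))
  schedule$w_final * (1 - exp(-pmax(t - schedule$t_onset, 0) / schedule$tau_perfusion))
}

#' Simulate a drug-induction time course
#'
#' One sweep per `sweep_interval`, each simulated with the CMI weight
#' `w(t)` at that sweep's start time. I_peak is non-increasing after drug
#' onset while I_300 stays constant (the CMI signature).
#'
#' @param params Baseline [gating_params()] (its `w` is overridden per sweep).
#' @param schedule An [induction_schedule()].
#' @param protocol A single-step [voltage_protocol()].
#' @param cm Membrane capacitance (pF).
#' @return A list of [current_trace()] objects, one per sweep, with the
#'   sweep time (s) in an attribute `sweep_times`.
#' @export
simulate_induction_timecourse <- function(params, schedule,
                                          protocol = voltage_protocol(),
                                          cm = 10) {
  stopifnot(inherits(schedule, "induction_schedule"))
  times <- (seq_len(schedule$n_sweeps) - 1) * schedule$sweep_interval
  sweeps <- lapply(times, function(tt) {
    p <- params
    p$w <- induction_weight(tt, schedule)
    simulate_step_current(p, protocol, "Ca", cm,
                          meta = sprintf("induction t=%gs", tt))
  })
  attr(sweeps, "sweep_times") <- times
  sweeps
}

#' Simulate a run-down time course
#'
#' Progressive loss of functional channels: conductance scaled by
#' `exp(-t/decay_tau)` per sweep. S_Ca is constant across sweeps; I_peak
#' and I_300 decline with identical fractional loss (the conventional
#' inhibition signature).
#'
#' @param params Baseline [gating_params()].
#' @param decay_tau Run-down time constant (s); `Inf` gives constant sweeps.
#' @param protocol A single-step [voltage_protocol()].
#' @param cm Membrane capacitance (pF).
#' @param n_sweeps Number of sweeps.
#' @param sweep_interval Interval between sweeps (s).
#' @return A list of [current_trace()] objects with attribute `sweep_times`.
#' @export
simulate_rundown_timecourse <- function(params, decay_tau,
                                        protocol = voltage_protocol(),
                                        cm = 10, n_sweeps = 21,
                                        sweep_interval = 30) {
  if (decay_tau <= 0) stop("decay_tau must be positive")
  times <- (seq_len(n_sweeps) - 1) * sweep_interval
  sweeps <- lapply(times, function(tt) {
    p <- params
    p$g_density <- p$g_density * exp(-tt / decay_tau)
    simulate_step_current(p, protocol, "Ca", cm,
                          meta = sprintf("rundown t=%gs", tt))
  })
  attr(sweeps, "sweep_times") <- times
  sweeps
}
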