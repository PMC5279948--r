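# closed-form oracle for the step-current indices, written directly from
# the model definitions (instantaneous activation); independent of the
# trace-based pipeline it checks
oracle_step_indices <- function(params, v = -10, cm = 10,
                                family_v = seq(-70, 50, by = 10)) {
  m_inf <- function(x) 1 / (1 + exp(-(x - params$v_half) / params$k_slope))
  drive <- function(x) (x - params$e_rev) * m_inf(x)
  u <- abs(drive(v)) / max(abs(drive(family_v)))
  r_inf <- 1 - (1 - params$r_inf_max) * u
  h <- function(t) r_inf + (1 - r_inf) * exp(-t / params$tau_cdi)
  r_pin <- h(300)
  mix <- function(t) (1 - params$w) * h(t) + params$w * r_pin
  i_peak <- cm * params$g_density * drive(v) * mix(0)
  list(
    i_peak = i_peak,
    r50 = mix(50) / mix(0),
    r300 = mix(300) / mix(0),
    s_ca = 1 - mix(50) / mix(0),
    j_peak = i_peak / cm
  )
}

# brute-force grid oracle for the calibration problem: scan (r_inf, tau_cdi)
# at the given resolution, derive w from the peak-fraction equation, and
# minimize the summed squared residuals of the three observables
grid_calibrate_oracle <- function(s_b, pf, s_c,
                                  r_step = 1e-3, tau_step = 0.05) {
  r50 <- 1 - s_b
  r_grid <- seq(r_step, r50 - r_step, by = r_step)
  tau_grid <- seq(5, 40, by = tau_step)
  best <- NULL; best_val <- Inf
  for (r in r_grid) {
    w <- (1 - pf) / (1 - r)
    if (w <= 0 || w > 1) next
    r50_hat <- r + (1 - r) * exp(-50 / tau_grid)
    res1 <- (r50_hat - r50)^2
    res2 <- ((w * r + (1 - w) * r50_hat) / pf - (1 - s_c))^2
    val <- res1 + res2
    k <- which.min(val)
    if (val[k] < best_val) {
      best_val <- val[k]
      best <- c(r_inf = r, tau_cdi = tau_grid[k], w = w)
    }
  }
  list(par = best, objective = best_val)
}

# a noiseless analytic Ca2+ trace with a prescribed inactivation law,
# bypassing the simulator entirely
analytic_trace <- function(h_fun, amp = -100, duration = 300, dt = 0.5,
                           cm = 10, carrier = "Ca", v = -10) {
  t <- seq(0, duration, by = dt)
  current_trace(t, amp * h_fun(t), carrier, cm,
                voltage_protocol(step_potential = v, step_duration = duration,
                                 sample_interval = dt))
}

# per-cell indices averaged over a cohort (the per-cell-then-average
# convention), returned as a trace_indices object for the classifier
mean_indices <- function(cohort) {
  idx <- lapply(cohort, function(cell) trace_indices(cell$traces[[1]]))
  avg <- function(f) mean(vapply(idx, `[[`, numeric(1), f))
  structure(
    list(i_peak = avg("i_peak"), t_peak = avg("t_peak"),
         i_50 = avg("i_50"), i_100 = avg("i_100"), i_300 = avg("i_300"),
         i_1000 = NA_real_, r_50 = avg("r_50"), r_300 = avg("r_300"),
         s_ca = avg("s_ca"), j_peak = avg("j_peak"), j_300 = avg("j_300"),
         carrier = idx[[1]]$carrier, cm = avg("cm")),
    class = "trace_indices"
  )
}
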