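test_that("Boltzmann activation has the right midpoint, saturation and values", {
  p <- gating_params(v_half = -20, k_slope = 7)
  expect_equal(activation_curve(-20, p), 0.5)
  expect_equal(activation_curve(1e4, p), 1.0)
  # midpoint + one slope factor: 1/(1 + e^-1), frozen to high precision
  expect_equal(activation_curve(-13, p), 0.7310585786300049, tolerance = 1e-12)
  expect_true(all(diff(activation_curve(seq(-80, 60, 2), p)) > 0))
})

test_that("CDI gate starts at 1, decays to the voltage-scaled floor", {
  p <- gating_params()
  expect_equal(cdi_gate(0, -10, p), 1.0)
  expect_equal(cdi_gate(1e6, -10, p), p$r_inf_max, tolerance = 1e-12)
  # 0.20 + 0.80 * exp(-50/15), frozen from direct evaluation
  expect_equal(cdi_gate(50, -10, p), 0.2285391946778019, tolerance = 1e-12)
  expect_error(cdi_gate(-1, -10, p), "t must be")
  # the floor is shallower away from the voltage of maximal current
  expect_gt(cdi_floor(40, p), cdi_floor(-10, p))
})

test_that("baseline simulated Ca2+ trace reproduces the calibrated indices", {
  tr <- simulate_step_current(gating_params(), voltage_protocol())
  ix <- trace_indices(tr)
  expect_equal(ix$s_ca, 0.77, tolerance = 0.005)
  expect_equal(ix$j_peak, -20, tolerance = 1e-9)
  # indices agree with the closed-form oracle
  or <- oracle_step_indices(gating_params())
  expect_equal(ix$i_peak, or$i_peak, tolerance = 1e-6)
  expect_equal(ix$r_50, or$r50, tolerance = 1e-6)
  expect_equal(ix$r_300, or$r300, tolerance = 1e-6)
})

test_that("the CMI mixture attenuates peak and S_Ca but pins I300", {
  base <- trace_indices(simulate_step_current(gating_params(), voltage_protocol()))
  cmi <- trace_indices(simulate_step_current(gating_params(w = 0.8125),
                                             voltage_protocol()))
  expect_equal(abs(cmi$i_peak) / abs(base$i_peak), 0.35, tolerance = 1e-6)
  expect_equal(cmi$s_ca, 0.41, tolerance = 0.01)
  expect_equal(cmi$i_300, base$i_300, tolerance = 1e-12)
  # ultrastrong CMI: flat trace at the end-stage level
  flat <- trace_indices(simulate_step_current(gating_params(w = 1),
                                              voltage_protocol()))
  expect_equal(flat$s_ca, 0)
  expect_equal(flat$i_peak, flat$i_300)
  expect_equal(flat$i_300, base$i_300, tolerance = 1e-12)
})

test_that("Ba2+ traces inactivate only by slow VDI", {
  tr <- simulate_step_current(gating_params(), voltage_protocol(), "Ba")
  ix <- trace_indices(tr)
  expect_equal(ix$r_50, exp(-50 / 1640), tolerance = 1e-9)
  expect_true(is.na(ix$s_ca))
})

test_that("mixture weight inverts the peak-reduction relation", {
  expect_equal(mixture_weight_for_peak_fraction(1, 0.2), 0)
  expect_equal(mixture_weight_for_peak_fraction(0.2, 0.2), 1)
  expect_equal(mixture_weight_for_peak_fraction(0.35, 0.20), 0.8125)
  expect_error(mixture_weight_for_peak_fraction(0.10, 0.20), "below the end-stage floor")
  # closed form agrees with scanning simulated peak ratios on a fine w grid
  base_peak <- abs(trace_indices(
    simulate_step_current(gating_params(), voltage_protocol()))$i_peak)
  ws <- seq(0, 1, by = 1e-2)
  fracs <- vapply(ws, function(w) {
    abs(trace_indices(simulate_step_current(gating_params(w = w),
                                            voltage_protocol()))$i_peak) / base_peak
  }, numeric(1))
  w_hat <- ws[which.min(abs(fracs - 0.35))]
  expect_equal(mixture_weight_for_peak_fraction(0.35, cdi_gate(300, -10, gating_params())),
               w_hat, tolerance = 1e-2)
})

test_that("calibration solves the printed index triple and round-trips", {
  cal <- calibrate_cdi_params(0.77, 0.35, 0.41)
  expect_equal(cal$r_inf_max, 0.20, tolerance = 0.01)
  expect_equal(cal$w, 0.81, tolerance = 0.01)
  expect_equal(cal$tau_cdi, 15, tolerance = 0.1)
  # brute-force 2-D grid oracle lands on the same parameters
  g <- grid_calibrate_oracle(0.77, 0.35, 0.41)
  expect_equal(unname(g$par["r_inf"]), cal$r_inf_max, tolerance = 2e-3)
  expect_equal(unname(g$par["tau_cdi"]), cal$tau_cdi, tolerance = 0.1)
  expect_equal(unname(g$par["w"]), cal$w, tolerance = 5e-3)
  # forward-simulate the calibrated parameters and recover the inputs
  p0 <- gating_params(tau_cdi = cal$tau_cdi, r_inf_max = cal$r_inf_max, w = 0)
  p1 <- gating_params(tau_cdi = cal$tau_cdi, r_inf_max = cal$r_inf_max, w = cal$w)
  i0 <- trace_indices(simulate_step_current(p0, voltage_protocol()))
  i1 <- trace_indices(simulate_step_current(p1, voltage_protocol()))
  expect_equal(i0$s_ca, 0.77, tolerance = 0.01)
  expect_equal(abs(i1$i_peak) / abs(i0$i_peak), 0.35, tolerance = 0.01)
  expect_equal(i1$s_ca, 0.41, tolerance = 0.01)
})

test_that("calibration round-trips generating parameters and flags infeasible triples", {
  gen <- list(tau_cdi = 22, r_inf_max = 0.15, w = 0.6)
  p0 <- gating_params(tau_cdi = gen$tau_cdi, r_inf_max = gen$r_inf_max, w = 0)
  p1 <- gating_params(tau_cdi = gen$tau_cdi, r_inf_max = gen$r_inf_max, w = gen$w)
  i0 <- trace_indices(simulate_step_current(p0, voltage_protocol()))
  i1 <- trace_indices(simulate_step_current(p1, voltage_protocol()))
  cal <- calibrate_cdi_params(i0$s_ca, abs(i1$i_peak) / abs(i0$i_peak), i1$s_ca)
  expect_equal(cal$tau_cdi, gen$tau_cdi, tolerance = 0.01 * gen$tau_cdi)
  expect_equal(cal$r_inf_max, gen$r_inf_max, tolerance = 0.01)
  expect_equal(cal$w, gen$w, tolerance = 0.01)
  # CMI end current cannot sit above the baseline r50 level
  expect_error(calibrate_cdi_params(0.5, 0.8, 0.3), "infeasible")
  expect_error(calibrate_cdi_params(0.77, 1.5, 0.41), "peak_fraction")
  expect_error(calibrate_cdi_params(0.77, 0.35, 0.9), "s_ca_cmi")
})

test_that("conventional block scales amplitudes but not gating", {
  p <- gating_params()
  expect_identical(apply_block(p, 0), p)
  base <- trace_indices(simulate_step_current(p, voltage_protocol()))
  blk <- trace_indices(simulate_step_current(apply_block(p, 0.28), voltage_protocol()))
  expect_equal(abs(blk$i_peak) / abs(base$i_peak), 0.72, tolerance = 1e-12)
  expect_equal(abs(blk$i_300) / abs(base$i_300), 0.72, tolerance = 1e-12)
  expect_equal(blk$s_ca, base$s_ca, tolerance = 1e-10)
  twice <- apply_block(apply_block(p, 0.5), 0.5)
  expect_equal(twice$g_density, p$g_density * 0.25)
  expect_error(apply_block(p, 1), "block_fraction")
})

test_that("induction time course attenuates peak while I300 stays constant", {
  sched <- induction_schedule(t_onset = 60, tau_perfusion = 75,
                              w_final = 0.8125, n_sweeps = 21,
                              sweep_interval = 30)
  sweeps <- simulate_induction_timecourse(gating_params(), sched)
  idx <- lapply(sweeps, trace_indices)
  peaks <- vapply(idx, function(x) abs(x$i_peak), numeric(1))
  i300 <- vapply(idx, function(x) abs(x$i_300), numeric(1))
  after <- attr(sweeps, "sweep_times") >= sched$t_onset
  expect_true(all(diff(peaks[after]) <= 1e-12))
  expect_lt(max(abs(i300 - i300[1]) / i300[1]), 1e-9)
  # plateau reproduces the printed endpoint values
  final <- idx[[length(idx)]]
  expect_equal(final$s_ca, 0.41, tolerance = 0.015)
  expect_equal(peaks[length(peaks)] / peaks[1], 0.35, tolerance = 0.01)
  # control group: no drug, no change
  ctrl <- simulate_induction_timecourse(
    gating_params(), induction_schedule(w_final = 0, n_sweeps = 5))
  cpeaks <- vapply(ctrl, function(s) abs(trace_indices(s)$i_peak), numeric(1))
  expect_true(all(abs(cpeaks - cpeaks[1]) < 1e-12))
})

test_that("run-down scales both indices together, leaving S_Ca untouched", {
  sweeps <- simulate_rundown_timecourse(gating_params(), decay_tau = 120,
                                        n_sweeps = 5, sweep_interval = 120)
  idx <- lapply(sweeps, trace_indices)
  peaks <- vapply(idx, function(x) abs(x$i_peak), numeric(1))
  i300 <- vapply(idx, function(x) abs(x$i_300), numeric(1))
  s_ca <- vapply(idx, function(x) x$s_ca, numeric(1))
  expect_equal(peaks[2] / peaks[1], exp(-1), tolerance = 1e-9)
  expect_equal(peaks / peaks[1], i300 / i300[1], tolerance = 1e-12)
  expect_lt(max(abs(s_ca - s_ca[1])), 1e-10)
})

test_that("constant-I300, peak monotonicity and floor hold across the w range", {
  ws <- seq(0, 1, by = 0.1)
  idx <- lapply(ws, function(w) {
    trace_indices(simulate_step_current(gating_params(w = w), voltage_protocol()))
  })
  i300 <- vapply(idx, function(x) x$i_300, numeric(1))
  expect_lt(max(abs(i300 - i300[1]) / abs(i300[1])), 1e-9)
  peaks <- vapply(idx, function(x) abs(x$i_peak), numeric(1))
  s_ca <- vapply(idx, function(x) x$s_ca, numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(s_ca) < 0))
  expect_true(all(vapply(idx, function(x) abs(x$i_peak) >= abs(x$i_300), logical(1))))
})

test_that("the CDI strength profile mirrors the current-density profile", {
  fam_ca <- simulate_step_family(gating_params())
  fam_ba <- simulate_step_family(gating_params(), carrier = "Ba")
  prof <- cdi_profile(fam_ca, fam_ba)
  vga <- vga_profile(fam_ca)
  expect_equal(prof$voltages[which.max(1 - prof$r50_ca)],
               vga$voltages[which.max(abs(vga$j_peak))])
  expect_equal(prof$s_ca_at_minus10, 0.77, tolerance = 0.005)
})

test_that("protocol and parameter validation reject malformed inputs", {
  expect_error(voltage_protocol(step_duration = -1), "step_duration")
  expect_error(voltage_protocol(sample_interval = 10), "sample_interval")
  expect_error(gating_params(r_inf_max = 1.2), "r_inf_max")
  expect_error(gating_params(w = 2), "w must")
  expect_error(gating_params(tau_vdi = 10), "tau_vdi")
  expect_error(simulate_step_current(gating_params(), voltage_protocol(), cm = -1),
               "cm must be positive")
  expect_error(
    simulate_step_current(gating_params(),
                          voltage_protocol(step_potential = c(-10, 0))),
    "single step")
})
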