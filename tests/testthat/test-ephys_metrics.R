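test_that("trace indices read the analytic inactivation law correctly", {
  p <- gating_params()
  tr <- analytic_trace(function(t) 0.20 + 0.80 * exp(-t / 15))
  ix <- trace_indices(tr)
  expect_equal(ix$r_300, 0.2000, tolerance = 1e-4)
  expect_equal(ix$r_50, 0.20 + 0.80 * exp(-50 / 15), tolerance = 1e-9)
  expect_equal(ix$t_peak, 0)
  # flat trace: no inactivation at all
  flat <- analytic_trace(function(t) rep(1, length(t)))
  expect_equal(trace_indices(flat)$r_50, 1)
  expect_equal(trace_indices(flat)$s_ca, 0)
  # coverage errors
  short <- current_trace(seq(0, 40, 0.4), rep(-5, 101), "Ca", 10)
  expect_error(trace_indices(short), "too short")
  # i_1000 absent for a 300-ms trace
  expect_true(is.na(ix$i_1000))
})

test_that("S_Ca is invariant under positive trace scaling", {
  tr <- simulate_step_current(gating_params(), voltage_protocol())
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    tr2 <- tr
    tr2$current <- tr2$current * k
    expect_equal(trace_indices(tr2)$s_ca, trace_indices(tr)$s_ca,
                 tolerance = 1e-10)
  }
})

test_that("voltage profiles carry the inactivation and density structure", {
  fam_ca0 <- simulate_step_family(gating_params())
  fam_ca1 <- simulate_step_family(gating_params(w = 1))
  fam_ba <- simulate_step_family(gating_params(), carrier = "Ba")
  prof0 <- cdi_profile(fam_ca0, fam_ba)
  prof1 <- cdi_profile(fam_ca1, fam_ba)
  expect_equal(prof0$r50_ba, rep(exp(-50 / 1640), length(prof0$voltages)),
               tolerance = 1e-9)
  expect_true(all(1 - prof1$r50_ca < 1e-9))       # no CDI at ultrastrong CMI
  expect_gt(max(prof0$cdi_diff), 0.7)             # strong CDI at the U minimum
  vga0 <- vga_profile(fam_ca0)
  vga1 <- vga_profile(simulate_step_family(gating_params(w = 0.8125)))
  expect_equal(vga0$j_ca_at_minus10, -20, tolerance = 1e-9)
  expect_equal(vga1$j_300, vga0$j_300, tolerance = 1e-9)  # constant J300 in w
  vga_blk <- vga_profile(simulate_step_family(apply_block(gating_params(), 0.28)))
  expect_equal(vga_blk$j_peak, 0.72 * vga0$j_peak, tolerance = 1e-12)
  expect_error(cdi_profile(fam_ca0[1:3], fam_ba), "voltage grid")
})

test_that("time-course summaries separate CMI from conventional signatures", {
  sched <- induction_schedule(w_final = 0.8125, n_sweeps = 15)
  tc <- timecourse_summary(simulate_induction_timecourse(gating_params(), sched))
  expect_true(all(diff(tc$s_ca) <= 1e-12))
  expect_true(all(diff(tc$i_peak_norm) <= 1e-12))
  expect_true(all(abs(tc$i_300_norm - 1) < 0.01))
  rd <- timecourse_summary(simulate_rundown_timecourse(
    gating_params(), decay_tau = 300, n_sweeps = 10))
  expect_lt(max(abs(rd$s_ca - rd$s_ca[1])), 1e-10)
  expect_equal(rd$i_peak_norm, rd$i_300_norm, tolerance = 1e-12)
  ctrl <- timecourse_summary(simulate_induction_timecourse(
    gating_params(), induction_schedule(w_final = 0, n_sweeps = 5)))
  expect_true(all(abs(ctrl$s_ca / ctrl$s_ca[1] - 1) < 1e-12))
  expect_true(all(abs(ctrl$i_peak_norm - 1) < 1e-12))
  expect_error(timecourse_summary(list()), "at least 2")
})

test_that("the inhibition classifier reproduces the decision table exactly", {
  base <- trace_indices(simulate_step_current(gating_params(), voltage_protocol()))
  cmi <- trace_indices(simulate_step_current(gating_params(w = 0.8125),
                                             voltage_protocol()))
  blk <- trace_indices(simulate_step_current(apply_block(gating_params(), 0.28),
                                             voltage_protocol()))
  expect_equal(classify_inhibition(base, cmi), "cmi")
  expect_equal(classify_inhibition(base, blk), "conventional")
  expect_equal(classify_inhibition(base, base), "none")
})

test_that("classification is exact on the noisy 4-scenario x 5-seed grid", {
  protocol <- voltage_protocol()
  scen <- list(
    cmi = list(params = gating_params(w = 0.8125), label = "cmi"),
    block = list(params = apply_block(gating_params(), 0.28), label = "conventional"),
    rundown = list(params = apply_block(gating_params(), 0.4), label = "conventional"),
    control = list(params = gating_params(), label = "none")
  )
  n_correct <- 0; n_total <- 0
  for (seed in 1:5) {
    base_ix <- mean_indices(make_cell_cohort(
      cohort_spec(5, seed = 1000 + seed, cm_cv = 0, amplitude_cv = 0,
                  noise_rms = 0.02), protocol))
    for (s in names(scen)) {
      test_ix <- mean_indices(make_cell_cohort(
        cohort_spec(5, seed = 2000 + 17 * seed + match(s, names(scen)),
                    cm_cv = 0, amplitude_cv = 0, noise_rms = 0.02,
                    params = scen[[s]]$params, scenario = s), protocol))
      got <- classify_inhibition(base_ix, test_ix)
      n_total <- n_total + 1
      n_correct <- n_correct + (got == scen[[s]]$label)
    }
  }
  expect_equal(n_correct, n_total)   # 100% over 4 scenarios x 5 seeds
})

test_that("cohort-mean S_Ca is robust to 2% recording noise", {
  cohort <- make_cell_cohort(cohort_spec(10, seed = 99, noise_rms = 0.02))
  s_ca <- vapply(cohort, function(cell) trace_indices(cell$traces[[1]])$s_ca,
                 numeric(1))
  noiseless <- trace_indices(simulate_step_current(gating_params(),
                                                   voltage_protocol()))$s_ca
  expect_lt(abs(mean(s_ca) - noiseless), 0.02)
})
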