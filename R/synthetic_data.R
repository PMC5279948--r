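# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so cohort generation never perturbs user code
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# lognormal draws with a given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic-cohort specification
#'
#' Describes a cohort of simulated cells: how many, the seed, the
#' capacitance and expression-level variability (lognormal, so strictly
#' positive and right-skewed as in transient-transfection systems), the
#' additive recording-noise level, and the gating scenario.
#'
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param cm_mean Mean membrane capacitance (pF).
#' @param cm_cv Coefficient of variation of capacitance.
#' @param amplitude_cv Coefficient of variation of the per-cell conductance
#'   scale (expression variability).
#' @param noise_rms Additive Gaussian noise SD as a fraction of each
#'   trace's peak amplitude.
#' @param scenario Label for the gating scenario.
#' @param params [gating_params()] for the scenario (defaults to baseline).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells, seed = 1, cm_mean = 20, cm_cv = 0.3,
                        amplitude_cv = 0.3, noise_rms = 0.02,
                        scenario = "baseline", params = gating_params()) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (cm_cv < 0 || amplitude_cv < 0 || noise_rms < 0) {
    stop("cv and noise values must be >= 0")
  }
  structure(
    list(n_cells = n_cells, seed = seed, cm_mean = cm_mean, cm_cv = cm_cv,
         amplitude_cv = amplitude_cv, noise_rms = noise_rms,
         scenario = scenario, params = params),
    class = "cohort_spec"
  )
}

add_trace_noise <- function(trace, noise_rms) {
  if (noise_rms <= 0) return(trace)
  sd <- noise_rms * max(abs(trace$current))
  trace$current <- trace$current + stats::rnorm(length(trace$current), 0, sd)
  trace
}

#' Generate a synthetic patch-clamp cohort
#'
#' Per cell: capacitance and conductance scale drawn lognormally, traces
#' simulated with [simulate_step_current()] (one per step potential in the
#' protocol), then additive Gaussian noise with SD equal to
#' `noise_rms` times the cell's peak amplitude. Identical seeds give
#' identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [voltage_protocol()]; a multi-step protocol yields a
#'   trace family per cell.
#' @return A list of cells, each a list with `cm`, `scale` and `traces`
#'   (list of [current_trace()]).
#' @export
make_cell_cohort <- function(spec, protocol = voltage_protocol()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    cms <- rlnorm_mean_cv(spec$n_cells, spec$cm_mean, spec$cm_cv)
    scales <- rlnorm_mean_cv(spec$n_cells, 1, spec$amplitude_cv)
    lapply(seq_len(spec$n_cells), function(i) {
      p <- spec$params
      p$g_density <- p$g_density * scales[i]
      traces <- if (length(protocol$step_potential) > 1) {
        simulate_step_family(p, protocol, "Ca", cms[i], meta = spec$scenario)
      } else {
        list(simulate_step_current(p, protocol, "Ca", cms[i],
                                   meta = spec$scenario))
      }
      traces <- lapply(traces, add_trace_noise, noise_rms = spec$noise_rms)
      list(cm = cms[i], scale = scales[i], traces = traces)
    })
  })
}

#' Generate a synthetic FRET cohort
#'
#' Cells with `d_free` drawn log-uniformly over `d_range` (so the
#' saturating isotherm is sampled evenly in log-donor) and
#' `fr = fr_model(d_free) + N(0, noise_sd^2)`, floored at 0.5.
#'
#' @param n Number of cells.
#' @param kd,fr_max Generating isotherm parameters.
#' @param d_range Length-2 increasing positive range of `d_free`.
#' @param noise_sd Additive Gaussian noise SD on `fr` (default 0.15).
#' @param seed Integer seed.
#' @return A data frame with columns `d_free`, `fr`.
#' @export
#' @examples
#' cells <- make_fret_cohort(60, kd = 1135, fr_max = 3.7,
#'                           d_range = c(100, 30000), seed = 7)
#' fit_binding(bin_cells(cells, 5))
make_fret_cohort <- function(n, kd, fr_max, d_range = c(100, 30000),
                             noise_sd = 0.15, seed = 1) {
  if (length(d_range) != 2 || d_range[1] <= 0 || d_range[2] <= d_range[1]) {
    stop("d_range must be a positive increasing pair")
  }
  with_local_seed(seed, {
    d_free <- exp(stats::runif(n, log(d_range[1]), log(d_range[2])))
    fr <- fr_model(d_free, kd, fr_max) + stats::rnorm(n, 0, noise_sd)
    data.frame(d_free = d_free, fr = pmax(fr, 0.5))
  })
}

#' Generate a cohort of drug-induction time courses
#'
#' One induction sweep series per cell, with per-cell capacitance and
#' expression variability and independent per-sweep recording noise.
#'
#' @param spec A [cohort_spec()].
#' @param schedule An [induction_schedule()].
#' @param protocol A single-step [voltage_protocol()].
#' @return A list of cells, each a list with `cm`, `scale`, `sweeps`
#'   (list of noisy [current_trace()]s with attribute `sweep_times`).
#' @export
make_induction_dataset <- function(spec, schedule,
                                   protocol = voltage_protocol()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(schedule, "induction_schedule"))
  with_local_seed(spec$seed, {
    cms <- rlnorm_mean_cv(spec$n_cells, spec$cm_mean, spec$cm_cv)
    scales <- rlnorm_mean_cv(spec$n_cells, 1, spec$amplitude_cv)
    lapply(seq_len(spec$n_cells), function(i) {
      p <- spec$params
      p$g_density <- p$g_density * scales[i]
      sweeps <- simulate_induction_timecourse(p, schedule, protocol, cms[i])
      st <- attr(sweeps, "sweep_times")
      sweeps <- lapply(sweeps, add_trace_noise, noise_rms = spec$noise_rms)
      attr(sweeps, "sweep_times") <- st
      list(cm = cms[i], scale = scales[i], sweeps = sweeps)
    })
  })
}
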