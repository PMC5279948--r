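#' FRET two-hybrid binding isotherm
#'
#' The saturating one-site binding relation between the FRET ratio and the
#' equivalent free-donor fluorescence intensity:
#' \deqn{FR = 1 + \frac{FR_{max} - 1}{1 + K_d / D_{free}}}
#' `FR` rises from 1 at vanishing donor to `fr_max` at saturation, with
#' half-saturation at `d_free = kd`.
#'
#' @param d_free Free-donor intensity (arbitrary donor-cube units), > 0.
#' @param kd Effective dissociation constant, same units as `d_free`, > 0.
#' @param fr_max Maximal FRET ratio (> 1 for a true binder).
#' @return The FRET ratio(s).
#' @export
#' @examples
#' fr_model(1135, kd = 1135, fr_max = 3.7)  # half-saturation
fr_model <- function(d_free, kd, fr_max) {
  if (any(d_free <= 0)) stop("d_free must be positive")
  if (kd <= 0) stop("kd must be positive")
  1 + (fr_max - 1) / (1 + kd / d_free)
}

#' Average cells in bins of adjacent donor intensity
#'
#' Reproduces the display convention for binding plots: cells are sorted
#' ascending by `d_free` and consecutive groups of `bin_size` are averaged
#' componentwise. A final partial bin is kept if it holds at least
#' `ceiling(bin_size/2)` cells; smaller remainders are dropped.
#'
#' @param cells Data frame with columns `d_free` and `fr` (one row per cell).
#' @param bin_size Number of adjacent cells per bin (default 5).
#' @return A data frame of binned `(d_free, fr)` points.
#' @export
bin_cells <- function(cells, bin_size = 5) {
  stopifnot(is.data.frame(cells), all(c("d_free", "fr") %in% names(cells)))
  if (nrow(cells) == 0) stop("empty cell table")
  if (bin_size < 1) stop("bin_size must be >= 1")
  cells <- cells[order(cells$d_free), , drop = FALSE]
  n <- nrow(cells)
  grp <- (seq_len(n) - 1) %/% bin_size
  sizes <- table(grp)
  keep <- as.integer(names(sizes))[sizes >= ceiling(bin_size / 2)]
  out <- do.call(rbind, lapply(keep, function(g) {
    sub <- cells[grp == g, , drop = FALSE]
    data.frame(d_free = mean(sub$d_free), fr = mean(sub$fr))
  }))
  rownames(out) <- NULL
  out
}

#' Fit the binding isotherm by nonlinear least squares
#'
#' Unweighted least-squares fit of [fr_model()] over `(kd, fr_max)`, with
#' `kd` parameterized on the log scale to preserve positivity and improve
#' conditioning. Initialization: `kd` at the median `d_free`, `fr_max` at
#' the largest observed `fr`. An optional nonparametric bootstrap
#' (resampling points with replacement) gives a percentile interval for
#' `kd`.
#'
#' The fit is refused as unidentifiable when the points span less than a
#' 10-fold `d_free` range, or when the fitted dynamic range `fr_max - 1`
#' is below 3 times the residual RMS (flat data, indicative of very weak
#' binding).
#'
#' @param points Data frame with columns `d_free`, `fr` (binned points or
#'   raw cells); at least 4 rows.
#' @param init Optional numeric `c(kd, fr_max)` starting values.
#' @param n_boot Number of bootstrap refits for the `kd` interval
#'   (0 = skip).
#' @param seed Optional seed for the bootstrap resampling.
#' @return An object of class `binding_fit`: list with `kd`, `fr_max`,
#'   `rss`, `n_points`, `converged`, and `kd_interval` (95% percentile
#'   bootstrap, or `NULL`).
#' @export
#' @examples
#' pts <- data.frame(d_free = 10^seq(2, 4.5, length.out = 12))
#' pts$fr <- fr_model(pts$d_free, kd = 1135, fr_max = 3.7)
#' fit_binding(pts)
fit_binding <- function(points, init = NULL, n_boot = 0, seed = NULL) {
  stopifnot(is.data.frame(points), all(c("d_free", "fr") %in% names(points)))
  if (nrow(points) < 4) stop("need at least 4 points to fit")
  rng <- range(points$d_free)
  if (rng[2] / rng[1] < 10) {
    stop("unidentifiable fit: d_free range spans less than 10-fold")
  }
  fit_once <- function(dat) {
    start <- if (is.null(init)) {
      list(lkd = log(stats::median(dat$d_free)), fr_max = max(dat$fr))
    } else {
      list(lkd = log(init[1]), fr_max = init[2])
    }
    fit <- minpack.lm::nlsLM(
      fr ~ 1 + (fr_max - 1) / (1 + exp(lkd) / d_free),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    est <- stats::coef(fit)
    list(kd = unname(exp(est["lkd"])), fr_max = unname(est["fr_max"]),
         rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv)
  }
  main <- fit_once(points)
  resid_rms <- sqrt(main$rss / nrow(points))
  if (main$fr_max - 1 < 3 * resid_rms) {
    stop("unidentifiable fit: dynamic range (fr_max - 1) below 3x residual RMS (flat data)")
  }
  kd_interval <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    kds <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(points), replace = TRUE)
      tryCatch(fit_once(points[idx, , drop = FALSE])$kd,
               error = function(e) NA_real_)
    }, numeric(1))
    kds <- kds[is.finite(kds)]
    if (length(kds) >= 10) {
      kd_interval <- unname(stats::quantile(kds, c(0.025, 0.975)))
    }
  }
  structure(
    list(kd = main$kd, fr_max = main$fr_max, rss = main$rss,
         n_points = nrow(points), converged = main$converged,
         kd_interval = kd_interval),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> kd = %.4g, fr_max = %.3f, rss = %.3g, n = %d%s\n",
              x$kd, x$fr_max, x$rss, x$n_points,
              if (!is.null(x$kd_interval))
                sprintf(", kd 95%% CI [%.4g, %.4g]",
                        x$kd_interval[1], x$kd_interval[2]) else ""))
  invisible(x)
}

#' Compare two binding affinities
#'
#' Smaller `kd` means higher affinity. Ratios within `equiv_band` of 1 are
#' reported as equivalent ("no appreciable change").
#'
#' @param fit_a,fit_b Converged [fit_binding()] results.
#' @param equiv_band Relative band around ratio 1 treated as a tie
#'   (default 0.10).
#' @return A list with `ratio = kd_b / kd_a` and `ordering`, one of
#'   `"a_higher_affinity"`, `"b_higher_affinity"`, `"equivalent"`.
#' @export
compare_affinity <- function(fit_a, fit_b, equiv_band = 0.10) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("cannot compare: one of the fits did not converge")
  }
  ratio <- fit_b$kd / fit_a$kd
  ordering <- if (abs(ratio - 1) <= equiv_band) {
    "equivalent"
  } else if (ratio > 1) "a_higher_affinity" else "b_higher_affinity"
  list(ratio = ratio, ordering = ordering)
}
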