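#' Profile-chi-squared confidence contours for a fitted parameter
#'
#' Scans one parameter over a grid, re-optimizing all other free parameters
#' at each grid value, and reports where the profile chi-squared crosses the
#' confidence threshold. Following the FitSpace ratio convention, the
#' default boundary 0.98 places the threshold at
#' `chi2_threshold = chi2_min / 0.98`: the confidence region is the set of
#' parameter values whose best attainable chi-squared stays within that
#' ratio of the global minimum.
#'
#' A parameter whose profile never crosses the threshold on one side within
#' the grid is reported as a one-sided bound (mirroring literature entries
#' such as "k3 > 10 1/s"); a profile flat on both sides flags the parameter
#' as unidentifiable.
#'
#' @param fit A `"kinetic_fit"` (from [global_fit()]) or `"mm_fit"` (from
#'   [fit_michaelis_menten()]).
#' @param parameter Name of the parameter to profile (must be free in the
#'   fit).
#' @param grid Numeric vector of parameter values to scan. Defaults to 41
#'   log-spaced points spanning `spread` times the estimate either side.
#' @param boundary Chi-squared ratio boundary in (0, 1); default 0.98.
#' @param spread Multiplicative half-range of the default grid.
#' @param n_grid Number of default grid points.
#' @return An object of class `"contour_result"`: tibble `profile` with
#'   columns `value`, `chi2`; `lower`, `upper` (possibly `-Inf`/`Inf` with
#'   `lower_bounded`/`upper_bounded` flags); `threshold`; `estimate`.
#' @export
confidence_contours <- function(fit, parameter, grid = NULL, boundary = 0.98,
                                spread = 4, n_grid = 41) {
  UseMethod("confidence_contours")
}

#' @export
confidence_contours.kinetic_fit <- function(fit, parameter, grid = NULL,
                                            boundary = 0.98, spread = 4,
                                            n_grid = 41) {
  if (!parameter %in% fit$free) {
    abort(paste0("parameter is not free in this fit: ", parameter),
      class = "dhalokin_contract_error"
    )
  }
  if (!fit$converged) {
    warn("profiling a non-converged fit; contours may be unreliable")
  }
  est <- fit$estimates[[parameter]]
  if (is.null(grid)) grid <- default_profile_grid(est, spread, n_grid)
  check_profile_grid(grid, est)
  others <- setdiff(fit$free, parameter)

  profile_chi2 <- vapply(grid, function(val) {
    rates_i <- fit$rates
    coeffs_i <- fit$coeffs
    upd <- apply_free_params(rates_i, coeffs_i, setNames(val, parameter))
    if (length(others)) {
      refit <- tryCatch(
        global_fit(fit$dataset, fit$mechanism, upd$rates, upd$coeffs,
          free = others, conc_adjust = fit$conc_adjust, n_starts = 1
        ),
        error = function(e) NULL
      )
      if (is.null(refit)) return(NA_real_)
      refit$chi2_min
    } else {
      # no nuisance parameters: evaluate chi2 directly
      rates2 <- upd$rates
      coeffs2 <- upd$coeffs
      chi2_of(fit$dataset, fit$mechanism, rates2, coeffs2)
    }
  }, numeric(1))

  finish_contour(parameter, grid, profile_chi2, fit$chi2_min, est, boundary)
}

#' @export
confidence_contours.mm_fit <- function(fit, parameter = c("kcat", "Km"),
                                       grid = NULL, boundary = 0.98,
                                       spread = 4, n_grid = 41) {
  parameter <- match.arg(parameter)
  est <- fit[[parameter]]
  if (is.null(grid)) grid <- default_profile_grid(est, spread, n_grid)
  check_profile_grid(grid, est)
  ir <- fit$data
  E0 <- fit$E0
  other <- setdiff(c("kcat", "Km"), parameter)

  profile_chi2 <- vapply(grid, function(val) {
    fn <- function(p) {
      th <- setNames(c(val, exp(p)), c(parameter, other))
      (ir$v_uM_per_s - th[["kcat"]] * E0 * ir$S_uM / (th[["Km"]] + ir$S_uM)) / ir$sigma
    }
    f <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = log(fit[[other]]), fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
    if (is.null(f)) NA_real_ else f$deviance
  }, numeric(1))

  finish_contour(parameter, grid, profile_chi2, fit$chi2_min, est, boundary)
}

#' Confidence limits from an explicit chi-squared profile
#'
#' Lower-level entry point used when the profile chi-squared of a parameter
#' can be evaluated directly (e.g. a one-parameter model with a closed-form
#' chi-squared). Applies the same threshold convention and crossing
#' interpolation as [confidence_contours()].
#'
#' @param chi2_fn Function mapping a parameter value to its (profile)
#'   chi-squared.
#' @param estimate The chi-squared-minimizing value.
#' @param grid Grid of parameter values bracketing `estimate`.
#' @param boundary Chi-squared ratio boundary in (0, 1); default 0.98.
#' @return A `"contour_result"`.
#' @export
chi2_profile <- function(chi2_fn, estimate, grid, boundary = 0.98) {
  check_profile_grid(grid, estimate)
  chi2 <- vapply(grid, chi2_fn, numeric(1))
  finish_contour("theta", grid, chi2, chi2_fn(estimate), estimate, boundary)
}

default_profile_grid <- function(est, spread, n_grid) {
  exp(seq(log(est / spread), log(est * spread), length.out = n_grid))
}

check_profile_grid <- function(grid, est) {
  if (min(grid) > est || max(grid) < est) {
    abort("profile grid must bracket the point estimate",
      class = "dhalokin_contract_error"
    )
  }
  invisible(grid)
}

chi2_of <- function(dataset, mechanism, rates, coeffs) {
  res <- numeric(0)
  if (nrow(dataset$traces)) {
    for (tr in split(dataset$traces, dataset$traces$trace_id)) {
      st <- simulate_timecourse(mechanism, rates,
        E0 = tr$E0_uM[1], S0 = tr$S0_uM[1],
        times = union(0, tr$time_s)
      )
      sig <- apply_observable(st, coeffs)
      mod <- sig$signal[match(tr$time_s, sig$time_s)]
      res <- c(res, (tr$signal - mod) / tr$sigma)
    }
  }
  if (nrow(dataset$initial_rates)) {
    ir <- dataset$initial_rates
    kc <- derived_kcat(rates, mechanism)
    km <- derived_km(rates, mechanism)
    v <- kc * ir$E_uM * ir$S_uM / (km + ir$S_uM)
    res <- c(res, (ir$v_uM_per_s - v) / ir$sigma)
  }
  sum(res^2)
}

finish_contour <- function(parameter, grid, chi2, chi2_min, est, boundary) {
  if (boundary <= 0 || boundary >= 1) {
    abort("boundary must be in (0, 1)", class = "dhalokin_config_error")
  }
  threshold <- chi2_min / boundary
  prof <- tibble(value = grid, chi2 = pmax(chi2, chi2_min))
  ok <- !is.na(prof$chi2)

  cross <- function(side) {
    g <- prof[ok, ]
    if (side == "lower") {
      g <- g[g$value <= est, ]
      g <- g[order(g$value), ]
    } else {
      g <- g[g$value >= est, ]
      g <- g[order(g$value), ]
    }
    if (nrow(g) < 2) return(NA_real_)
    above <- g$chi2 > threshold
    if (side == "lower") {
      # walking up from the low end: limit is the last downward crossing
      idx <- which(above[-nrow(g)] & !above[-1])
      if (!length(idx)) return(NA_real_)
      i <- idx[length(idx)]
    } else {
      idx <- which(!above[-nrow(g)] & above[-1])
      if (!length(idx)) return(NA_real_)
      i <- idx[1]
    }
    # log-linear interpolation of the crossing
    x1 <- log(g$value[i]); x2 <- log(g$value[i + 1])
    y1 <- g$chi2[i]; y2 <- g$chi2[i + 1]
    if (y2 == y1) return(g$value[i])
    exp(x1 + (threshold - y1) * (x2 - x1) / (y2 - y1))
  }

  lower <- cross("lower")
  upper <- cross("upper")
  structure(
    list(
      parameter = parameter,
      profile = prof,
      estimate = est,
      chi2_min = chi2_min,
      threshold = threshold,
      boundary = boundary,
      lower = if (is.na(lower)) -Inf else lower,
      upper = if (is.na(upper)) Inf else upper,
      lower_bounded = !is.na(lower),
      upper_bounded = !is.na(upper)
    ),
    class = "contour_result"
  )
}

#' @export
print.contour_result <- function(x, ...) {
  lab <- if (x$lower_bounded && x$upper_bounded) {
    sprintf("[%.4g, %.4g]", x$lower, x$upper)
  } else if (x$lower_bounded) {
    sprintf("> %.4g (upper limit unbounded in grid)", x$lower)
  } else if (x$upper_bounded) {
    sprintf("< %.4g (lower limit unbounded in grid)", x$upper)
  } else {
    "unidentifiable (flat profile)"
  }
  cat("<contour_result> ", x$parameter, " = ", signif(x$estimate, 4),
    ", chi2 ratio boundary ", x$boundary, ": ", lab, "\n",
    sep = ""
  )
  invisible(x)
}
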