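# Global fitting of kinetic datasets.
#
# Parameterization: all rate constants and the positive observable factors
# are optimized on the log scale (rates are positive; the transform also
# conditions the Levenberg-Marquardt steps). Baselines and per-trace
# concentration-adjustment factors stay on the natural scale.

# parameters that live on the natural scale during optimization
.natural_scale_params <- "baseline"

free_param_values <- function(rates, coeffs, free) {
  vals <- numeric(0)
  for (nm in free) {
    v <- if (nm %in% names(unclass(rates))) {
      rates[[nm]]
    } else if (!is.null(coeffs) && nm %in% names(unclass(coeffs))) {
      coeffs[[nm]]
    } else {
      abort(paste0("free parameter not found in rates or coefficients: ", nm),
        class = "dhalokin_config_error"
      )
    }
    vals <- c(vals, setNames(v, nm))
  }
  vals
}

apply_free_params <- function(rates, coeffs, theta_nat) {
  for (nm in names(theta_nat)) {
    if (nm %in% names(unclass(rates))) {
      rates[[nm]] <- theta_nat[[nm]]
    } else {
      coeffs[[nm]] <- theta_nat[[nm]]
    }
  }
  list(rates = rates, coeffs = coeffs)
}

to_internal <- function(theta_nat) {
  ifelse(names(theta_nat) %in% .natural_scale_params, theta_nat, log(theta_nat))
}

to_natural <- function(theta_int) {
  out <- ifelse(names(theta_int) %in% .natural_scale_params, theta_int, exp(theta_int))
  setNames(out, names(theta_int))
}

#' Globally fit a kinetic mechanism to a heterogeneous dataset
#'
#' Minimizes the sigma-normalized chi-squared
#' \deqn{\chi^2 = \sum_i \left(\frac{obs_i - model_i}{\sigma_i}\right)^2}
#' over stopped-flow traces (model evaluated by ODE integration of the
#' mechanism per trace, mapped through the observable model) and, when
#' present, steady-state initial-rate blocks (Michaelis-Menten form with
#' `kcat`/`Km` derived from the current microscopic constants). Optimization
#' is Levenberg-Marquardt ([minpack.lm::nls.lm()]) on the residual vector,
#' with positive parameters log-transformed. A deterministic multi-start
#' (log-uniform perturbations of the initial guess) guards against local
#' minima; the best start is reported.
#'
#' Standard errors come from the covariance of the estimates at the optimum,
#' `cov = s2 * (J'J)^{-1}` with `s2 = chi2_min / (n - p)`, transformed back
#' to the natural scale by the delta method. A singular `J'J` flags the fit
#' as unidentifiable and leaves the SEs `NA`.
#'
#' Optional per-trace multiplicative concentration adjustments (`+-10%`,
#' reflecting pipetting accuracy) can be freed with `conc_adjust = TRUE`;
#' they multiply the nominal `S0` of each trace and are bounded to
#' `[0.9, 1.1]`.
#'
#' @param dataset A `"kinetic_dataset"` (see the generators).
#' @param mechanism A `"mechanism"` object.
#' @param rates Initial [rate_parameters()]; values of parameters not listed
#'   in `free` are held fixed.
#' @param coeffs Observable coefficients ([signal_coefficients()]) or a
#'   species name for the identity observable.
#' @param free Character vector of parameter names to optimize (rate
#'   constants and/or observable factors).
#' @param conc_adjust Free bounded per-trace substrate-concentration factors.
#' @param n_starts Number of multi-start restarts (>= 1); restart
#'   perturbations are drawn deterministically from `restart_seed`.
#' @param restart_spread Log10 half-width of the restart perturbations.
#' @param restart_seed Seed for the restart draws.
#' @param max_iter Maximum LM iterations per start.
#' @return An object of class `"kinetic_fit"`: estimates, standard errors,
#'   `chi2_min`, covariance, convergence info, and the data needed by
#'   [confidence_contours()].
#' @export
global_fit <- function(dataset, mechanism, rates, coeffs = NULL,
                       free = c("k2", "k3"),
                       conc_adjust = FALSE,
                       n_starts = 5, restart_spread = 0.5,
                       restart_seed = 1L, max_iter = 200) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (!length(free)) {
    abort("at least one free parameter is required", class = "dhalokin_contract_error")
  }
  has_traces <- nrow(dataset$traces) > 0
  has_rates <- nrow(dataset$initial_rates) > 0
  if (has_traces && any(dataset$traces$sigma <= 0)) {
    abort("every trace point needs sigma > 0", class = "dhalokin_contract_error")
  }
  if (has_rates && any(dataset$initial_rates$sigma <= 0)) {
    abort("every rate point needs sigma > 0", class = "dhalokin_contract_error")
  }

  theta0_nat <- free_param_values(rates, coeffs, free)
  if (any(theta0_nat <= 0 & !names(theta0_nat) %in% .natural_scale_params)) {
    abort("initial guesses for log-scale parameters must be > 0",
      class = "dhalokin_contract_error"
    )
  }

  trace_groups <- if (has_traces) split(dataset$traces, dataset$traces$trace_id) else list()
  n_tr <- length(trace_groups)
  n_conc <- if (conc_adjust) n_tr else 0

  residual_fn <- function(par_int) {
    theta_nat <- to_natural(setNames(par_int[seq_along(theta0_nat)], names(theta0_nat)))
    upd <- apply_free_params(rates, coeffs, theta_nat)
    adj <- if (n_conc) par_int[length(theta0_nat) + seq_len(n_conc)] else rep(1, n_tr)
    res <- numeric(0)
    if (has_traces) {
      for (i in seq_len(n_tr)) {
        tr <- trace_groups[[i]]
        st <- tryCatch(
          simulate_timecourse(
            mechanism, upd$rates,
            E0 = tr$E0_uM[1], S0 = tr$S0_uM[1] * adj[i],
            times = union(0, tr$time_s)
          ),
          error = function(e) NULL
        )
        if (is.null(st)) {
          res <- c(res, rep(1e6, nrow(tr)))
          next
        }
        sig <- apply_observable(st, upd$coeffs)
        mod <- sig$signal[match(tr$time_s, sig$time_s)]
        res <- c(res, (tr$signal - mod) / tr$sigma)
      }
    }
    if (has_rates) {
      ir <- dataset$initial_rates
      kc <- derived_kcat(upd$rates, mechanism)
      km <- derived_km(upd$rates, mechanism)
      v <- kc * ir$E_uM * ir$S_uM / (km + ir$S_uM)
      res <- c(res, (ir$v_uM_per_s - v) / ir$sigma)
    }
    res
  }

  start_int <- c(to_internal(theta0_nat), if (n_conc) rep(1, n_conc))
  lower <- c(rep(-Inf, length(theta0_nat)), if (n_conc) rep(0.9, n_conc))
  upper <- c(rep(Inf, length(theta0_nat)), if (n_conc) rep(1.1, n_conc))

  starts <- list(start_int)
  if (n_starts > 1) {
    perturb <- with_seed(restart_seed, function() {
      purrr::map(seq_len(n_starts - 1), function(i) {
        d <- runif(length(theta0_nat), -restart_spread, restart_spread) * log(10)
        d[names(theta0_nat) %in% .natural_scale_params] <- 0
        c(start_int[seq_along(theta0_nat)] + d, if (n_conc) rep(1, n_conc))
      })
    })
    starts <- c(starts, perturb)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, fn = residual_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort("all optimization starts failed", class = "dhalokin_fit_error")
  }

  par_hat <- best$par
  theta_hat <- to_natural(setNames(par_hat[seq_along(theta0_nat)], names(theta0_nat)))
  chi2_min <- best$deviance
  n_points <- length(best$fvec)
  n_params <- length(par_hat)
  converged <- best$info %in% 1:4

  # covariance on the internal scale, delta-method back to natural
  jtj <- best$hessian
  se_nat <- setNames(rep(NA_real_, length(theta_hat)), names(theta_hat))
  cov_nat <- NULL
  identifiable <- TRUE
  dof <- max(n_points - n_params, 1)
  cv <- tryCatch(solve(jtj) * chi2_min / dof, error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    identifiable <- FALSE
  } else {
    scale <- ifelse(names(theta_hat) %in% .natural_scale_params, 1, theta_hat)
    k <- seq_along(theta_hat)
    cov_nat <- cv[k, k, drop = FALSE] * tcrossprod(scale)
    dimnames(cov_nat) <- list(names(theta_hat), names(theta_hat))
    se_nat <- sqrt(diag(cov_nat))
  }

  conc_factors <- if (n_conc) {
    setNames(par_hat[length(theta0_nat) + seq_len(n_conc)], names(trace_groups))
  } else {
    NULL
  }

  upd <- apply_free_params(rates, coeffs, theta_hat)
  structure(
    list(
      estimates = theta_hat,
      standard_errors = se_nat,
      chi2_min = chi2_min,
      n_points = n_points,
      n_params = n_params,
      covariance = cov_nat,
      converged = converged,
      identifiable = identifiable,
      iterations = best$niter,
      conc_factors = conc_factors,
      rates = upd$rates,
      coeffs = upd$coeffs,
      free = free,
      mechanism = mechanism,
      dataset = dataset,
      conc_adjust = conc_adjust,
      residual_fn = residual_fn
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> chi2_min = ", signif(x$chi2_min, 6),
    " (", x$n_points, " points, ", x$n_params, " parameters)",
    if (!x$converged) "  [NOT CONVERGED]",
    "\n",
    sep = ""
  )
  for (nm in names(x$estimates)) {
    cat(sprintf(
      "  %-9s %12.6g +- %.3g\n", nm, x$estimates[[nm]],
      x$standard_errors[[nm]]
    ))
  }
  if (!x$identifiable) cat("  (singular covariance: SEs undetermined)\n")
  invisible(x)
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Weighted nonlinear least squares of `v = kcat * E0 * S / (Km + S)` with
#' `kcat` and `Km` on the log scale, residuals normalized by the per-point
#' sigma. SEs from the scaled covariance at the optimum.
#'
#' If the substrate series does not bracket `Km` the pair (kcat, Km) is not
#' separately identifiable: with only saturating data (`min(S) > 10 * Km`)
#' the fit reports `kcat = mean(v)/E0` and flags `Km`; with only
#' sub-saturating data (`max(S) < Km / 10`) only the slope `kcat/Km` is
#' reported.
#'
#' @param initial_rates Tibble with columns `S_uM`, `v_uM_per_s` and
#'   optionally `sigma` (defaults to 1) and `E_uM` (overridden by `E0` if
#'   given).
#' @param E0 Enzyme concentration (uM); taken from the data when omitted.
#' @param start Optional named start values `c(kcat =, Km =)`.
#' @return An object of class `"mm_fit"` with `kcat`, `Km`, `se_kcat`,
#'   `se_Km`, `kcat_over_Km`, `chi2_min`, `identifiable`, `flag`.
#' @export
fit_michaelis_menten <- function(initial_rates, E0 = NULL, start = NULL) {
  ir <- as_tibble(initial_rates)
  if (is.null(E0)) {
    if (!"E_uM" %in% names(ir)) {
      abort("supply E0 or an E_uM column", class = "dhalokin_contract_error")
    }
    E0 <- ir$E_uM
  }
  if (length(E0) == 1) E0 <- rep(E0, nrow(ir))
  if (!"sigma" %in% names(ir)) ir$sigma <- 1
  if (dplyr::n_distinct(ir$S_uM) < 3) {
    abort("need >= 3 distinct substrate concentrations",
      class = "dhalokin_contract_error"
    )
  }
  S <- ir$S_uM
  v <- ir$v_uM_per_s
  w <- ir$sigma

  if (is.null(start)) {
    vmax0 <- max(v)
    km0 <- S[which.min(abs(v - vmax0 / 2))]
    start <- c(kcat = max(vmax0 / mean(E0), 1e-9), Km = max(km0, min(S[S > 0])))
  }
  fn <- function(p) {
    kc <- exp(p[1])
    km <- exp(p[2])
    (v - kc * E0 * S / (km + S)) / w
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = log(unname(start)), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ))
  kcat <- exp(fit$par[1])
  Km <- exp(fit$par[2])
  chi2_min <- fit$deviance
  dof <- max(length(v) - 2, 1)
  cv <- tryCatch(solve(fit$hessian) * chi2_min / dof, error = function(e) NULL)
  se <- c(NA_real_, NA_real_)
  if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
    se <- sqrt(diag(cv)) * c(kcat, Km) # delta method from log scale
  }

  flag <- "ok"
  identifiable <- TRUE
  if (min(S) > 10 * Km) {
    flag <- "saturating_only"
    identifiable <- FALSE
    kcat <- mean(v / E0)
    se[1] <- sd(v / E0) / sqrt(length(v))
    se[2] <- NA_real_
  } else if (max(S) < Km / 10) {
    flag <- "subsaturating_only"
    identifiable <- FALSE
  }

  structure(
    list(
      kcat = kcat, Km = Km, se_kcat = se[1], se_Km = se[2],
      kcat_over_Km = kcat / Km,
      chi2_min = chi2_min, n_points = length(v),
      identifiable = identifiable, flag = flag,
      converged = fit$info %in% 1:4,
      covariance = cv, E0 = E0[1],
      data = ir
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> kcat = ", signif(x$kcat, 4), " +- ", signif(x$se_kcat, 3),
    " 1/s;  Km = ", signif(x$Km, 4), " +- ", signif(x$se_Km, 3), " uM\n",
    sep = ""
  )
  if (x$flag != "ok") cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}
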