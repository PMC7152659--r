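#' Tidy a global kinetic fit
#'
#' @param x A `"kinetic_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$standard_errors)
  )
}

#' @rdname tidy.kinetic_fit
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    chi2_min = x$chi2_min,
    n_points = x$n_points,
    n_params = x$n_params,
    reduced_chi2 = x$chi2_min / max(x$n_points - x$n_params, 1),
    converged = x$converged,
    identifiable = x$identifiable,
    iterations = x$iterations
  )
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `"mm_fit"`.
#' @param ... Unused.
#' @return A tibble with rows for `kcat` and `Km`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("kcat", "Km"),
    estimate = c(x$kcat, x$Km),
    std.error = c(x$se_kcat, x$se_Km)
  )
}

#' @rdname tidy.mm_fit
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    chi2_min = x$chi2_min,
    n_points = x$n_points,
    kcat_over_Km = x$kcat_over_Km,
    converged = x$converged,
    identifiable = x$identifiable,
    flag = x$flag
  )
}

#' Tidy a transition model
#'
#' @param x A `"transition_model"`.
#' @param ... Unused.
#' @return A tibble with one row per state: `state` (0-based label) and
#'   `equilibrium_probability`.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  tibble(
    state = x$states,
    equilibrium_probability = x$equilibrium_distribution
  )
}

#' @rdname tidy.transition_model
#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  ev <- Re(eigen(x$transition_matrix)$values)
  ev <- ev[order(-abs(ev))]
  t2 <- if (length(ev) > 1 && ev[2] > 0 && ev[2] < 1) -x$lag / log(ev[2]) else NA_real_
  tibble(
    n_states = nrow(x$transition_matrix),
    lag = x$lag,
    reversible = x$reversible,
    slowest_timescale = t2,
    n_dropped = length(x$dropped_states)
  )
}

#' Tidy a confidence-contour profile
#'
#' @param x A `"contour_result"`.
#' @param ... Unused.
#' @return The profile tibble (`value`, `chi2`) with the parameter name in
#'   a `parameter` column.
#' @method tidy contour_result
#' @export
tidy.contour_result <- function(x, ...) {
  dplyr::mutate(x$profile, parameter = x$parameter, .before = 1)
}

#' @rdname tidy.contour_result
#' @method glance contour_result
#' @export
glance.contour_result <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    estimate = x$estimate,
    lower = x$lower,
    upper = x$upper,
    lower_bounded = x$lower_bounded,
    upper_bounded = x$upper_bounded,
    chi2_min = x$chi2_min,
    threshold = x$threshold
  )
}
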