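# ggplot2 diagnostics for the main result types.

#' Plot observed vs fitted stopped-flow traces
#'
#' @param object A `"kinetic_fit"` with trace data.
#' @param ... Unused.
#' @return A ggplot object: points are observations, lines the fitted model,
#'   one panel per trace.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  tr <- object$dataset$traces
  if (!nrow(tr)) {
    abort("no traces in this fit", class = "dhalokin_contract_error")
  }
  fitted <- purrr::map_dfr(split(tr, tr$trace_id), function(g) {
    st <- simulate_timecourse(object$mechanism, object$rates,
      E0 = g$E0_uM[1], S0 = g$S0_uM[1], times = union(0, g$time_s)
    )
    sig <- apply_observable(st, object$coeffs)
    tibble(
      trace_id = g$trace_id[1], time_s = g$time_s,
      model = sig$signal[match(g$time_s, sig$time_s)]
    )
  })
  df <- dplyr::left_join(tr, fitted, by = c("trace_id", "time_s"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$signal)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "firebrick") +
    ggplot2::facet_wrap(~trace_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)")
}

#' Plot a Michaelis-Menten fit
#'
#' @param object An `"mm_fit"`.
#' @param ... Unused.
#' @return A ggplot object with the rate data and the fitted saturation
#'   curve.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  ir <- object$data
  s_grid <- exp(seq(log(min(ir$S_uM)), log(max(ir$S_uM)), length.out = 200))
  curve <- tibble(
    S_uM = s_grid,
    v_uM_per_s = object$kcat * object$E0 * s_grid / (object$Km + s_grid)
  )
  ggplot2::ggplot(ir, ggplot2::aes(.data$S_uM, .data$v_uM_per_s)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[S] (uM)", y = "v0 (uM/s)")
}

#' Plot a profile chi-squared contour
#'
#' @param object A `"contour_result"`.
#' @param ... Unused.
#' @return A ggplot object: the profile with the threshold and limits
#'   marked.
#' @method autoplot contour_result
#' @export
autoplot.contour_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile, ggplot2::aes(.data$value, .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$parameter, y = expression(chi^2))
  if (object$lower_bounded) {
    p <- p + ggplot2::geom_vline(xintercept = object$lower, linetype = 3)
  }
  if (object$upper_bounded) {
    p <- p + ggplot2::geom_vline(xintercept = object$upper, linetype = 3)
  }
  p
}

#' Plot implied-timescale curves
#'
#' @param its Output of [implied_timescales()].
#' @return A ggplot object, one line per timescale index; a plateau across
#'   lags indicates Markovian behaviour.
#' @export
plot_implied_timescales <- function(its) {
  df <- dplyr::filter(its, is.finite(.data$timescale))
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$timescale,
    colour = factor(.data$index)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag (frames)", y = "implied timescale (frames)", colour = "index")
}

#' Plot Chapman-Kolmogorov discrepancies
#'
#' @param ck Output of [ck_test()].
#' @return A ggplot bar chart of the max entrywise discrepancy per factor.
#' @export
plot_ck_test <- function(ck) {
  df <- purrr::map_dfr(ck, function(e) {
    tibble(factor = e$factor, max_discrepancy = e$max_discrepancy)
  })
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$factor), .data$max_discrepancy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "factor k", y = "max |T(tau)^k - T(k tau)|")
}

#' Plot NAC classification in the distance-angle plane
#'
#' @param classified Output of [classify_nac()].
#' @param criteria The criteria used (drawn as the acceptance window).
#' @return A ggplot object.
#' @export
plot_nac <- function(classified, criteria = nac_criteria()) {
  ggplot2::ggplot(classified, ggplot2::aes(.data$distance_A, .data$angle_deg,
    colour = .data$is_nac
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = criteria$max_distance,
      ymin = criteria$angle_min, ymax = criteria$angle_max,
      alpha = 0.1, fill = "forestgreen"
    ) +
    ggplot2::labs(x = "nucleophile-C distance (A)", y = "Nu-C-halide angle (deg)")
}
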