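#' Turnover number from microscopic rate constants
#'
#' For irreversible post-binding steps the steady-state turnover number is the
#' harmonic combination of the forward chemical/release rates: for the
#' four-step cycle `kcat = 1 / (1/k2 + 1/k3 + 1/k4)`, for the three-step
#' cycle `kcat = 1 / (1/k2 + 1/k3)`. A rate flagged `lower_bound_only` is
#' treated as +Inf, so the returned value is an upper bound on kcat.
#'
#' @param rates A [rate_parameters()] object.
#' @param mechanism A `"mechanism"` object.
#' @return kcat in 1/s.
#' @export
#' @examples
#' mech <- build_mechanism("four_step", rapid_equilibrium_binding = TRUE)
#' derived_kcat(rate_parameters(k2 = 330, k3 = 109, k4 = 3.2, Ks = 37000), mech)
derived_kcat <- function(rates, mechanism) {
  stopifnot(inherits(rates, "rate_parameters"), inherits(mechanism, "mechanism"))
  labs <- if (mechanism$scheme_id == "four_step") c("k2", "k3", "k4") else c("k2", "k3")
  vals <- vapply(labs, function(l) {
    v <- rates[[l]]
    if (identical(rates$status[[l]], "lower_bound_only")) Inf else v
  }, numeric(1))
  if (anyNA(vals)) {
    abort(paste0(
      "derived_kcat requires ", paste(labs, collapse = ", "),
      " (or lower_bound_only status)"
    ), class = "dhalokin_config_error")
  }
  if (any(vals == 0)) {
    warn("degenerate mechanism: a forward rate constant is 0, kcat = 0")
    return(0)
  }
  1 / sum(1 / vals)
}

#' Michaelis constant from microscopic rate constants
#'
#' Under rapid-equilibrium substrate binding (dissociation constant `Ks`,
#' substrate release much faster than chemistry) the steady-state Michaelis
#' constant of the catalytic cycle reduces to `Km = Ks * kcat / k2` for both
#' the four-step and the simplified three-step scheme. When explicit
#' `k1`/`k_minus1` are supplied instead of `Ks`, `Ks = k_minus1/k1` is used.
#'
#' @inheritParams derived_kcat
#' @return Km in uM.
#' @export
derived_km <- function(rates, mechanism) {
  stopifnot(inherits(rates, "rate_parameters"), inherits(mechanism, "mechanism"))
  k2 <- rates$k2
  if (is.na(k2)) abort("derived_km requires k2", class = "dhalokin_config_error")
  if (k2 == 0) {
    abort("degenerate mechanism: k2 = 0 leaves Km undefined",
      class = "dhalokin_degenerate_error"
    )
  }
  Ks <- if (!is.na(rates$Ks)) rates$Ks else ks_from_rates(rates$k1, rates$k_minus1)
  Ks * derived_kcat(rates, mechanism) / k2
}

#' Equilibrium dissociation constant from binding rate constants
#'
#' `Ks = k_minus1 / k1`, the equilibrium constant for dissociation of the
#' enzyme-substrate complex.
#'
#' @param k1 Association rate constant, 1/(uM s); must be > 0.
#' @param k_minus1 Dissociation rate constant, 1/s.
#' @return Ks in uM.
#' @export
#' @examples
#' ks_from_rates(2.4, 90) # 37.5 uM
ks_from_rates <- function(k1, k_minus1) {
  if (is.na(k1) || k1 == 0) {
    abort("k1 must be > 0 to form Ks = k_minus1/k1",
      class = "dhalokin_degenerate_error"
    )
  }
  k_minus1 / k1
}

#' Specificity constant kcat/Km
#'
#' Returns the exact quotient; when standard errors are supplied the SE of
#' the ratio is obtained by first-order independent-error propagation
#' ([propagate_ratio_error()]).
#'
#' @param kcat Turnover number (1/s).
#' @param Km Michaelis constant (uM); must be > 0.
#' @param se_kcat,se_Km Optional standard errors.
#' @return A tibble with columns `kcat_over_Km` and `se` (`se` is `NA` when
#'   no errors were supplied).
#' @export
#' @examples
#' specificity(57, 2350, 3, 30)
specificity <- function(kcat, Km, se_kcat = NULL, se_Km = NULL) {
  if (is.na(Km) || Km == 0) {
    abort("Km must be > 0 to form kcat/Km", class = "dhalokin_degenerate_error")
  }
  if (!is.null(se_kcat) && !is.null(se_Km)) {
    pr <- propagate_ratio_error(kcat, se_kcat, Km, se_Km)
    tibble(kcat_over_Km = pr$ratio, se = pr$se)
  } else {
    tibble(kcat_over_Km = kcat / Km, se = NA_real_)
  }
}

#' Identify the rate-limiting step of the catalytic cycle
#'
#' The rate-limiting step is the post-binding forward step with the smallest
#' rate constant (among `k2`, `k3`, `k4` for the four-step scheme; `k2`, `k3`
#' for the three-step scheme). Ties return all tied labels. Parameters
#' flagged `lower_bound_only` are treated as not limiting.
#'
#' @inheritParams derived_kcat
#' @return Character vector of step labels.
#' @export
#' @examples
#' mech <- build_mechanism("four_step", rapid_equilibrium_binding = TRUE)
#' rate_limiting_step(
#'   rate_parameters(k2 = 120, k3 = 139, k4 = 10, Ks = 21000), mech
#' )
rate_limiting_step <- function(rates, mechanism) {
  stopifnot(inherits(rates, "rate_parameters"), inherits(mechanism, "mechanism"))
  labs <- if (mechanism$scheme_id == "four_step") c("k2", "k3", "k4") else c("k2", "k3")
  vals <- vapply(labs, function(l) {
    if (identical(rates$status[[l]], "lower_bound_only")) Inf else rates[[l]]
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals) || all(!is.finite(vals))) {
    return(character(0))
  }
  names(vals)[vals == min(vals)]
}
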