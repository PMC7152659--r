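#' Fluorescence scaling coefficients
#'
#' The stopped-flow fluorescence signal is modelled as a weighted sum of
#' species concentrations with one scaling factor per distinct fluorescent
#' state. Two channels are supported:
#'
#' * `V1_ex500` (direct fluorophore excitation at 500 nm):
#'   `V1 = f * (S + ES + a*EI + b*(EP + P))`, where `a` and `b` capture the
#'   intensity change on forming the alkyl-enzyme intermediate and the
#'   product. Free and enzyme-bound product share `b` (same fluorophore
#'   state).
#' * `V2_ex280` (tryptophan excitation at 280 nm, FRET-modulated):
#'   `V2 = f * (S + o*ES + p*EI + q*EP + r*P)`, with `o` and `r` dominated by
#'   the FRET-efficiency change on binding/release and `p`, `q` empirical
#'   combinations of FRET and intensity changes.
#'
#' `baseline` is an optional additive instrument offset (same units as the
#' signal), zero by default.
#'
#' @param channel `"V1_ex500"` or `"V2_ex280"`.
#' @param f Overall scale (signal units per uM); must be >= 0.
#' @param a,b Intermediate / product factors (V1 only).
#' @param o,p,q,r Species factors (V2 only).
#' @param baseline Additive offset, default 0.
#' @return An object of class `"signal_coefficients"`.
#' @export
#' @examples
#' signal_coefficients("V1_ex500", f = 1, a = 2, b = 6)
signal_coefficients <- function(channel = c("V1_ex500", "V2_ex280"),
                                f = 1, a = NULL, b = NULL,
                                o = NULL, p = NULL, q = NULL, r = NULL,
                                baseline = 0) {
  channel <- match.arg(channel)
  if (f < 0) abort("f must be >= 0", class = "dhalokin_config_error")
  if (channel == "V1_ex500") {
    if (is.null(a) || is.null(b)) {
      abort("V1_ex500 requires factors a and b", class = "dhalokin_config_error")
    }
    if (!is.null(o) || !is.null(p) || !is.null(q) || !is.null(r)) {
      abort("V1_ex500 uses exactly {f, a, b}", class = "dhalokin_config_error")
    }
    co <- list(channel = channel, f = f, a = a, b = b, baseline = baseline)
  } else {
    if (is.null(o) || is.null(p) || is.null(q) || is.null(r)) {
      abort("V2_ex280 requires factors o, p, q and r",
        class = "dhalokin_config_error"
      )
    }
    if (!is.null(a) || !is.null(b)) {
      abort("V2_ex280 uses exactly {f, o, p, q, r}",
        class = "dhalokin_config_error"
      )
    }
    co <- list(
      channel = channel, f = f, o = o, p = p, q = q, r = r,
      baseline = baseline
    )
  }
  structure(co, class = "signal_coefficients")
}

check_states <- function(states) {
  need <- c("time_s", "S", "ES", "EI", "EP", "P")
  miss <- setdiff(need, names(states))
  if (length(miss)) {
    abort(paste0(
      "states must carry columns ",
      paste(need, collapse = ", "), "; missing: ",
      paste(miss, collapse = ", ")
    ), class = "dhalokin_contract_error")
  }
  invisible(states)
}

#' Fluorescence signal at direct fluorophore excitation (V1)
#'
#' Applies `V1 = f * (S + ES + a*EI + b*(EP + P)) + baseline` pointwise to a
#' species trajectory.
#'
#' @param states A species tibble as returned by [simulate_timecourse()].
#' @param coeffs A [signal_coefficients()] object with channel `V1_ex500`.
#' @return A tibble with columns `time_s` and `signal`.
#' @export
signal_v1 <- function(states, coeffs) {
  stopifnot(inherits(coeffs, "signal_coefficients"))
  if (coeffs$channel != "V1_ex500") {
    abort("signal_v1 requires channel V1_ex500", class = "dhalokin_contract_error")
  }
  check_states(states)
  tibble(
    time_s = states$time_s,
    signal = coeffs$f * (states$S + states$ES + coeffs$a * states$EI +
      coeffs$b * (states$EP + states$P)) + coeffs$baseline
  )
}

#' Fluorescence signal at tryptophan excitation (V2, FRET-modulated)
#'
#' Applies `V2 = f * (S + o*ES + p*EI + q*EP + r*P) + baseline` pointwise.
#'
#' @inheritParams signal_v1
#' @param coeffs A [signal_coefficients()] object with channel `V2_ex280`.
#' @return A tibble with columns `time_s` and `signal`.
#' @export
signal_v2 <- function(states, coeffs) {
  stopifnot(inherits(coeffs, "signal_coefficients"))
  if (coeffs$channel != "V2_ex280") {
    abort("signal_v2 requires channel V2_ex280", class = "dhalokin_contract_error")
  }
  check_states(states)
  tibble(
    time_s = states$time_s,
    signal = coeffs$f * (states$S + coeffs$o * states$ES +
      coeffs$p * states$EI + coeffs$q * states$EP +
      coeffs$r * states$P) + coeffs$baseline
  )
}

# Dispatch on channel; identity observable (observe a species column
# directly) is used for substrates with no fluorogenic model (DBE).
apply_observable <- function(states, coeffs) {
  if (is.character(coeffs) && length(coeffs) == 1) {
    check_states(states)
    if (!coeffs %in% names(states)) {
      abort(paste0("unknown species for identity observable: ", coeffs),
        class = "dhalokin_contract_error"
      )
    }
    return(tibble(time_s = states$time_s, signal = states[[coeffs]]))
  }
  stopifnot(inherits(coeffs, "signal_coefficients"))
  if (coeffs$channel == "V1_ex500") signal_v1(states, coeffs) else signal_v2(states, coeffs)
}
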