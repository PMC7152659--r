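#' Build a catalytic-cycle reaction mechanism
#'
#' Constructs the kinetic scheme of the haloalkane dehalogenase catalytic
#' cycle. The full four-step scheme is
#' \deqn{E + S \rightleftharpoons ES \to EI \to EP \rightleftharpoons E + P}
#' with rate constants `k1` (substrate binding), `k_minus1` (substrate
#' release), `k2` (SN2 nucleophilic substitution), `k3` (hydrolysis of the
#' alkyl-enzyme intermediate), `k4` (product release) and `k_minus4` (product
#' rebinding). The simplified three-step scheme collapses the last two steps
#' into a single step `k3` leading directly to free enzyme and product (used
#' when the fluorescence data cannot distinguish hydrolysis from product
#' release); it has no `EP` species.
#'
#' @param scheme_id `"four_step"` or `"three_step"`.
#' @param rapid_equilibrium_binding If `TRUE`, substrate binding is treated as
#'   a rapid pre-equilibrium described by the dissociation constant `Ks`
#'   rather than by the individual constants `k1` / `k_minus1`. Used for small
#'   substrates (DBE) whose binding is much faster than chemistry.
#'
#' @return An object of class `"mechanism"`: a list with `scheme_id`,
#'   `rapid_equilibrium_binding`, `species` (ordered character vector) and
#'   `steps` (a tibble with one row per elementary step).
#' @export
#' @examples
#' build_mechanism("four_step")
#' build_mechanism("three_step")
build_mechanism <- function(scheme_id = c("four_step", "three_step"),
                            rapid_equilibrium_binding = FALSE) {
  if (length(scheme_id) != 1L && !identical(scheme_id, c("four_step", "three_step"))) {
    scheme_id <- scheme_id[1]
  }
  scheme_id <- tryCatch(match.arg(scheme_id),
    error = function(e) {
      abort(paste0("unknown scheme_id: ", paste(scheme_id, collapse = ", ")),
        class = "dhalokin_config_error"
      )
    }
  )
  if (scheme_id == "four_step") {
    steps <- tibble::tribble(
      ~label,      ~reactants,     ~products,
      "k1",        list(c("E", "S")), list("ES"),
      "k_minus1",  list("ES"),        list(c("E", "S")),
      "k2",        list("ES"),        list("EI"),
      "k3",        list("EI"),        list("EP"),
      "k4",        list("EP"),        list(c("E", "P")),
      "k_minus4",  list(c("E", "P")), list("EP")
    )
    species <- c("E", "S", "ES", "EI", "EP", "P")
  } else {
    steps <- tibble::tribble(
      ~label,      ~reactants,        ~products,
      "k1",        list(c("E", "S")), list("ES"),
      "k_minus1",  list("ES"),        list(c("E", "S")),
      "k2",        list("ES"),        list("EI"),
      "k3",        list("EI"),        list(c("E", "P"))
    )
    species <- c("E", "S", "ES", "EI", "P")
  }
  structure(
    list(
      scheme_id = scheme_id,
      rapid_equilibrium_binding = isTRUE(rapid_equilibrium_binding),
      species = species,
      steps = steps
    ),
    class = "mechanism"
  )
}

#' @export
print.mechanism <- function(x, ...) {
  cat("<mechanism> ", x$scheme_id,
    if (x$rapid_equilibrium_binding) " (rapid-equilibrium binding)" else "",
    "\n",
    sep = ""
  )
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  steps:   ", paste(x$steps$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Microscopic rate constants of the catalytic cycle
#'
#' Bundles the rate constants of the catalytic cycle with their fitting
#' status. Units are fixed package-wide: bimolecular constants (`k1`,
#' `k_minus4`) in 1/(uM s), unimolecular constants (`k_minus1`, `k2`, `k3`,
#' `k4`) in 1/s, and the equilibrium dissociation constant `Ks` in uM.
#'
#' `status` flags each parameter as `"fixed"`, `"free"` or
#' `"lower_bound_only"`. A `lower_bound_only` rate (reported in the
#' literature as e.g. "> 10 1/s") is treated as +Inf in closed-form
#' derivations, so derived quantities become bounds rather than point
#' estimates.
#'
#' @param k1,k_minus1,k2,k3,k4,k_minus4 Rate constants (see units above).
#'   `k_minus4` defaults to 0 (irreversible product release).
#' @param Ks Dissociation constant of the ES complex (uM). Required when the
#'   mechanism uses rapid-equilibrium binding; in that case `k1`/`k_minus1`
#'   are derived implementation values (`k1 = 10` 1/(uM s),
#'   `k_minus1 = Ks * k1`).
#' @param status Optional named character vector overriding the default
#'   status (`"free"`) per parameter.
#'
#' @return An object of class `"rate_parameters"` (a named list).
#' @export
#' @examples
#' rate_parameters(k1 = 2.4, k_minus1 = 90, k2 = 5.9, k3 = 20, k4 = 20)
rate_parameters <- function(k1 = NA_real_, k_minus1 = NA_real_,
                            k2 = NA_real_, k3 = NA_real_, k4 = NA_real_,
                            k_minus4 = 0, Ks = NA_real_, status = NULL) {
  vals <- list(
    k1 = k1, k_minus1 = k_minus1, k2 = k2, k3 = k3, k4 = k4,
    k_minus4 = k_minus4, Ks = Ks
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && is.finite(v) && v < 0) {
      abort(paste0("rate constant ", nm, " must be >= 0, got ", v),
        class = "dhalokin_config_error"
      )
    }
  }
  st <- setNames(rep("free", length(vals)), names(vals))
  if (!is.null(status)) {
    bad <- setdiff(names(status), names(st))
    if (length(bad)) {
      abort(paste0("unknown parameter in status: ", paste(bad, collapse = ", ")),
        class = "dhalokin_config_error"
      )
    }
    ok <- status %in% c("fixed", "free", "lower_bound_only")
    if (!all(ok)) {
      abort("status values must be 'fixed', 'free' or 'lower_bound_only'",
        class = "dhalokin_config_error"
      )
    }
    st[names(status)] <- status
  }
  structure(c(vals, list(status = st)), class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters> (uM, s)\n")
  nm <- c("k1", "k_minus1", "k2", "k3", "k4", "k_minus4", "Ks")
  for (n in nm) {
    v <- x[[n]]
    if (is.na(v)) next
    tag <- x$status[[n]]
    cat(sprintf("  %-9s %12.6g  [%s]\n", n, v, tag))
  }
  invisible(x)
}

# Effective binding pair: rapid-equilibrium mechanisms substitute a fast
# explicit (k1, k_minus1) pair with k_minus1 = Ks * k1 so a single ODE path
# serves both regimes (relative error < 0.5% when k_minus1 >> k2).
effective_binding_rates <- function(mechanism, rates, k1_fast = 10) {
  if (mechanism$rapid_equilibrium_binding) {
    if (is.na(rates$Ks)) {
      abort("rapid-equilibrium mechanism requires Ks",
        class = "dhalokin_config_error"
      )
    }
    list(k1 = k1_fast, k_minus1 = rates$Ks * k1_fast)
  } else {
    if (is.na(rates$k1) || is.na(rates$k_minus1)) {
      abort("mechanism with explicit binding requires k1 and k_minus1",
        class = "dhalokin_config_error"
      )
    }
    list(k1 = rates$k1, k_minus1 = rates$k_minus1)
  }
}
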