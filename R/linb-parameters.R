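#' Published kinetic constants for LinB variants
#'
#' Steady-state and pre-steady-state kinetic constants reported for the
#' haloalkane dehalogenase LinB wild type and its tunnel-engineered variants
#' LinB32 (L177W in the main p1 tunnel) and LinB86 (L177W plus
#' W140A+F143L+I211L opening the auxiliary p3 tunnel) with three substrates:
#' 1,2-dibromoethane (DBE), a chloromethylated BODIPY dye (BDP) and
#' 4-(bromomethyl)-6,7-dimethoxycoumarin (COU). These literature values serve
#' as ground-truth parameter sets for the synthetic-data generators and as
#' reference points for analytic-consistency checks.
#'
#' DBE kinetics were resolved with rapid-equilibrium binding (only `Ks`
#' identifiable, in uM); BDP and COU resolved explicit `k1`/`k_minus1`. COU
#' data supported only the simplified three-step scheme (`k3` lumps
#' hydrolysis and product release; no `k4`). Entries reported only as lower
#' bounds ("> 10 1/s") carry `TRUE` in the corresponding `*_lb` column with
#' the bound in the value column.
#'
#' @param substrate Optional filter: `"DBE"`, `"BDP"` or `"COU"`.
#' @param variant Optional filter: `"LinBwt"`, `"LinB32"` or `"LinB86"`.
#' @return A tibble with one row per substrate-variant pair: steady-state
#'   `kcat` (1/s), `Km` (uM), `kcat_over_Km` (1/(uM s)) with standard errors,
#'   pre-steady-state `Ks` (uM), `k1` (1/(uM s)), `k_minus1`, `k2`, `k3`,
#'   `k4` (1/s) with standard errors, lower-bound flags, and the `scheme`
#'   each dataset supported.
#' @export
#' @examples
#' linb_kinetic_parameters("BDP", "LinBwt")
linb_kinetic_parameters <- function(substrate = NULL, variant = NULL) {
  tb <- tibble::tribble(
    ~substrate, ~variant, ~scheme, ~kcat, ~kcat_se, ~Km, ~Km_se,
    ~kcat_over_Km, ~kcat_over_Km_se,
    ~Ks, ~Ks_se, ~k1, ~k1_se, ~k_minus1, ~k_minus1_se,
    ~k2, ~k2_se, ~k3, ~k3_se, ~k4, ~k4_se, ~k3_lb, ~k4_lb,
    "DBE", "LinBwt", "four_step", 12, 4, 1700, 200, 0.007, 0.002,
    21000, 1000, NA, NA, NA, NA, 120, 10, 139, 5, 10, 1, FALSE, FALSE,
    "DBE", "LinB32", "four_step", 3.1, 0.1, 420, 30, 0.007, 0.001,
    37000, 2000, NA, NA, NA, NA, 330, 10, 109, 4, 3.2, 0.1, FALSE, FALSE,
    "DBE", "LinB86", "four_step", 57, 3, 2350, 30, 0.024, 0.001,
    17000, 1000, NA, NA, NA, NA, 350, 10, 340, 10, 70, 5, FALSE, FALSE,
    "BDP", "LinBwt", "four_step", 2.3, 0.2, 17, 1, 0.14, 0.01,
    38, 2, 2.4, 0.1, 90, 3, 5.9, 0.2, 10, NA, 10, NA, TRUE, TRUE,
    "BDP", "LinB32", "four_step", 1.1, 0.1, 24, 4, 0.046, 0.009,
    23, 1, 2.8, 0.1, 65, 1, 2.1, 0.1, 12, 1, 10, NA, FALSE, TRUE,
    "BDP", "LinB86", "four_step", 0.015, 0.001, 26, 2, 0.0006, 0.0001,
    70, 10, 0.024, 0.002, 1.7, 0.3, 0.18, 0.01, 0.011, 0.001, 18, 3, FALSE, FALSE,
    "COU", "LinBwt", "three_step", 3.9, 0.2, 0.7, 0.5, 6, 4,
    1, NA, 5.1, 0.6, NA, NA, 6.5, 0.1, 18, 1, NA, NA, FALSE, FALSE,
    "COU", "LinB32", "three_step", 0.68, 0.02, 13, 1, 0.052, 0.004,
    80, 9, 0.50, 0.05, 40, 2, 3.1, 0.2, 1.14, 0.03, NA, NA, FALSE, FALSE,
    "COU", "LinB86", "three_step", 0.89, 0.03, 30, 2, 0.030, 0.002,
    240, 30, 0.10, 0.01, 24, 2, 3.6, 0.2, 1.4, 0.1, NA, NA, FALSE, FALSE
  )
  if (!is.null(substrate)) tb <- tb[tb$substrate %in% substrate, ]
  if (!is.null(variant)) tb <- tb[tb$variant %in% variant, ]
  tb
}

#' Rate-parameter set for a published substrate-variant pair
#'
#' Convenience wrapper turning one row of [linb_kinetic_parameters()] into a
#' [rate_parameters()] object (with `lower_bound_only` status where the
#' literature reports only a bound). Lower-bound rates keep the bound as
#' their numeric value; closed-form derivations treat them as +Inf.
#'
#' @param substrate,variant Pair identifying the row.
#' @return A [rate_parameters()] object.
#' @export
linb_rates <- function(substrate, variant) {
  row <- linb_kinetic_parameters(substrate, variant)
  if (nrow(row) != 1) {
    abort("unknown substrate/variant pair", class = "dhalokin_config_error")
  }
  status <- c(
    k3 = if (isTRUE(row$k3_lb)) "lower_bound_only" else "free",
    k4 = if (isTRUE(row$k4_lb)) "lower_bound_only" else "free"
  )
  rate_parameters(
    k1 = row$k1, k_minus1 = row$k_minus1,
    k2 = row$k2, k3 = row$k3, k4 = row$k4,
    Ks = row$Ks, status = status
  )
}
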