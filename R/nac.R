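#' Near-attack-conformer geometric criteria
#'
#' The reactive binding pose (near-attack conformer, NAC) of a haloalkane in
#' the dehalogenase active site is defined geometrically: the nucleophile
#' (carboxylate oxygen of the catalytic aspartate) must sit within 3.41 A of
#' the attacked carbon, with a nucleophile-carbon-halide angle between 157
#' and 180 degrees (in-line SN2 attack). Both bounds are inclusive.
#'
#' @param max_distance Maximum nucleophile-carbon distance (A), > 0.
#' @param angle_min,angle_max Angle window (degrees), within [0, 180].
#' @return An object of class `"nac_criteria"`.
#' @export
nac_criteria <- function(max_distance = 3.41, angle_min = 157, angle_max = 180) {
  if (max_distance <= 0) {
    abort("max_distance must be > 0", class = "dhalokin_config_error")
  }
  if (angle_min < 0 || angle_max > 180 || angle_min > angle_max) {
    abort("need 0 <= angle_min <= angle_max <= 180",
      class = "dhalokin_config_error"
    )
  }
  structure(
    list(
      max_distance = max_distance,
      angle_min = angle_min, angle_max = angle_max
    ),
    class = "nac_criteria"
  )
}

#' Classify reaction-geometry frames as near-attack conformers
#'
#' A frame is a NAC iff `distance <= max_distance` and
#' `angle_min <= angle <= angle_max` (all bounds inclusive).
#'
#' @param geometries Data frame with columns `distance_A` (> 0) and
#'   `angle_deg` (within [0, 180]).
#' @param criteria A [nac_criteria()] object.
#' @return The input as a tibble with a logical `is_nac` column; the summary
#'   NAC fraction is attached as attribute `"nac_fraction"` and also
#'   retrievable with [nac_fraction()].
#' @export
#' @examples
#' g <- tibble::tibble(distance_A = c(3.41, 3.42), angle_deg = c(157, 170))
#' classify_nac(g)
classify_nac <- function(geometries, criteria = nac_criteria()) {
  stopifnot(inherits(criteria, "nac_criteria"))
  g <- as_tibble(geometries)
  need <- c("distance_A", "angle_deg")
  if (!all(need %in% names(g))) {
    abort("geometries must carry columns distance_A and angle_deg",
      class = "dhalokin_contract_error"
    )
  }
  if (any(g$distance_A <= 0)) {
    abort("distances must be > 0", class = "dhalokin_validation_error")
  }
  if (any(g$angle_deg < 0 | g$angle_deg > 180)) {
    abort("angles must lie in [0, 180] degrees",
      class = "dhalokin_validation_error"
    )
  }
  g$is_nac <- g$distance_A <= criteria$max_distance &
    g$angle_deg >= criteria$angle_min &
    g$angle_deg <= criteria$angle_max
  attr(g, "nac_fraction") <- mean(g$is_nac)
  g
}

#' @rdname classify_nac
#' @param classified Output of [classify_nac()].
#' @export
nac_fraction <- function(classified) {
  attr(classified, "nac_fraction") %||% mean(classified$is_nac)
}
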