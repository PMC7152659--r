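#' First-order error propagation for a ratio
#'
#' Standard error of `a / b` assuming independent errors:
#' `SE = |a/b| * sqrt((sa/a)^2 + (sb/b)^2)`; when `a = 0` the limit
#' `SE = sa / |b|` is used. This is the propagation applied to derived
#' constants such as `Ks = k_minus1 / k1` and `kcat / Km`.
#'
#' @param a,sa Numerator and its standard error.
#' @param b,sb Denominator and its standard error; `b` must be non-zero.
#' @return A tibble with columns `ratio` and `se`.
#' @export
#' @examples
#' propagate_ratio_error(90, 3, 2.4, 0.1) # Ks = 37.5 +- 2.0 uM
propagate_ratio_error <- function(a, sa, b, sb) {
  if (any(b == 0)) {
    abort("denominator b must be non-zero", class = "dhalokin_degenerate_error")
  }
  ratio <- a / b
  se <- ifelse(
    a == 0,
    sa / abs(b),
    abs(ratio) * sqrt((sa / a)^2 + (sb / b)^2)
  )
  tibble(ratio = ratio, se = se)
}

#' Welch's unequal-variances t-test from summary statistics
#'
#' Compares a kinetic constant between two enzyme variants given the fitted
#' means, dispersions and effective sample sizes. With `dispersion = "se"`
#' the inputs are standard errors of the means (`v_i = se_i^2`); with
#' `"sd"` they are sample standard deviations (`v_i = sd_i^2 / n_i`). The
#' statistic and degrees of freedom follow Welch-Satterthwaite:
#' \deqn{t = \frac{m_1 - m_2}{\sqrt{v_1 + v_2}}, \qquad
#'   \nu = \frac{(v_1 + v_2)^2}{v_1^2/(n_1-1) + v_2^2/(n_2-1)}}
#' Significance tiers mirror the usual table annotation: `"*"` for
#' p < 0.05, `"**"` for p < 0.01, `""` otherwise. No multiple-testing
#' correction is applied (raw tiers are reported; adjust externally if
#' needed).
#'
#' @param mean1,mean2 Group means.
#' @param disp1,disp2 Dispersions (SE of the mean, or SD — see
#'   `dispersion`), > 0.
#' @param n1,n2 Sample sizes, >= 2.
#' @param dispersion `"se"` or `"sd"`.
#' @return A one-row tibble: `estimate1`, `estimate2`, `t`, `df`, `p_value`,
#'   `significance`.
#' @export
#' @examples
#' welch_t_test(3.1, 0.1, 3, 12, 4, 3)
welch_t_test <- function(mean1, disp1, n1, mean2, disp2, n2,
                         dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  if (n1 < 2 || n2 < 2) {
    abort("n1 and n2 must be >= 2", class = "dhalokin_contract_error")
  }
  if (disp1 <= 0 || disp2 <= 0) {
    abort("dispersions must be > 0", class = "dhalokin_contract_error")
  }
  v1 <- if (dispersion == "se") disp1^2 else disp1^2 / n1
  v2 <- if (dispersion == "se") disp2^2 else disp2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  tibble(
    estimate1 = mean1, estimate2 = mean2,
    t = t_stat, df = df, p_value = p,
    significance = dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
  )
}
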