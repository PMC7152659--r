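test_that("noiseless global fits are self-consistent and deterministic", {
  fix <- bdp_wt_dataset(noise_sd = 0, dt = 0.02, t_end = 1)
  # start at truth: chi2 ~ 0, estimates unchanged
  f <- global_fit(fix$ds, fix$mech, fix$truth, fix$coeffs,
    free = c("k2", "k3", "a"), n_starts = 1
  )
  expect_lt(f$chi2_min, 1e-6)
  expect_equal(unname(f$estimates), c(5.9, 20, 2), tolerance = 1e-6)
  expect_true(f$converged)

  # start at 2x truth: multi-start recovery to 0.1%
  start <- rate_parameters(k1 = 2.4, k_minus1 = 90, k2 = 11.8, k3 = 40, k4 = 20)
  co0 <- signal_coefficients("V1_ex500", f = 1, a = 4, b = 6)
  f2 <- global_fit(fix$ds, fix$mech, start, co0,
    free = c("k2", "k3", "a"), n_starts = 5
  )
  expect_lt(max(abs(f2$estimates - c(5.9, 20, 2)) / c(5.9, 20, 2)), 1e-3)

  # determinism: same dataset, same start, same result
  f3 <- global_fit(fix$ds, fix$mech, start, co0,
    free = c("k2", "k3", "a"), n_starts = 5
  )
  expect_identical(f2$estimates, f3$estimates)
  expect_identical(f2$chi2_min, f3$chi2_min)

  expect_error(
    global_fit(fix$ds, fix$mech, fix$truth, fix$coeffs, free = character(0)),
    class = "dhalokin_contract_error"
  )
})

test_that("chi2 is invariant under joint rescaling of signals and sigmas", {
  fix <- bdp_wt_dataset(noise_sd = 0.01, dt = 0.05, t_end = 0.5, seed = 3)
  f1 <- global_fit(fix$ds, fix$mech, fix$truth, fix$coeffs,
    free = "k2", n_starts = 1
  )
  scaled <- fix$ds
  scaled$traces$signal <- scaled$traces$signal * 100
  scaled$traces$sigma <- scaled$traces$sigma * 100
  co_scaled <- signal_coefficients("V1_ex500", f = 100, a = 2, b = 6)
  f2 <- global_fit(scaled, fix$mech, fix$truth, co_scaled,
    free = "k2", n_starts = 1
  )
  expect_equal(f1$chi2_min, f2$chi2_min, tolerance = 1e-8)
  expect_equal(f1$estimates[["k2"]], f2$estimates[["k2"]], tolerance = 1e-6)
})

test_that("global fit recovers k2 within noise on a single-turnover dataset", {
  fix <- bdp_wt_dataset(noise_sd = 0.01, dt = 0.01, t_end = 1.5, seed = 42,
                        concs = c(2, 6, 10))
  start <- rate_parameters(k1 = 2.4, k_minus1 = 90, k2 = 12, k3 = 10, k4 = 20)
  co0 <- signal_coefficients("V1_ex500", f = 1.3, a = 1.3, b = 4)
  f <- global_fit(fix$ds, fix$mech, start, co0,
    free = c("k2", "k3", "a", "b", "f"), n_starts = 2
  )
  expect_true(f$converged)
  expect_lt(
    abs(f$estimates[["k2"]] - 5.9),
    2 * f$standard_errors[["k2"]] + 1e-12
  )
})

test_that("MM fitting recovers exact data and flags unidentifiable designs", {
  S <- c(100, 500, 1000, 5000, 20000)
  exact <- tibble::tibble(S_uM = S, v_uM_per_s = 57 * 0.2 * S / (2350 + S))
  f <- fit_michaelis_menten(exact, E0 = 0.2)
  expect_equal(f$kcat, 57, tolerance = 1e-6)
  expect_equal(f$Km, 2350, tolerance = 1e-6)
  expect_equal(f$flag, "ok")

  # saturating-only: kcat from the plateau, Km flagged
  sat <- tibble::tibble(
    S_uM = c(1e6, 2e6, 4e6),
    v_uM_per_s = 57 * 0.2 * c(1e6, 2e6, 4e6) / (2350 + c(1e6, 2e6, 4e6))
  )
  fs <- fit_michaelis_menten(sat, E0 = 0.2)
  expect_false(fs$identifiable)
  expect_equal(fs$flag, "saturating_only")
  expect_equal(fs$kcat * 0.2, mean(sat$v_uM_per_s), tolerance = 1e-6)
  expect_true(is.na(fs$se_Km))

  expect_error(
    fit_michaelis_menten(exact[1:2, ], E0 = 0.2),
    class = "dhalokin_contract_error"
  )
})

test_that("profile-chi2 limits match the closed form for a linear model", {
  # y = theta * x with known sigmas: chi2(theta) is exactly quadratic, so the
  # crossing of chi2_min/0.98 has a closed form
  set.seed(1)
  x <- seq(0.5, 5, length.out = 40)
  sigma <- 0.3
  theta_true <- 2
  y <- theta_true * x + rnorm(length(x), 0, sigma)
  theta_hat <- sum(x * y) / sum(x^2)
  chi2_fn <- function(th) sum(((y - th * x) / sigma)^2)
  chi2_min <- chi2_fn(theta_hat)
  half_width <- sqrt(chi2_min * (1 / 0.98 - 1) / sum((x / sigma)^2))

  grid <- seq(theta_hat - 3 * half_width, theta_hat + 3 * half_width,
    length.out = 2001
  )
  cr <- chi2_profile(chi2_fn, theta_hat, grid)
  expect_equal(cr$lower, theta_hat - half_width, tolerance = 1e-4)
  expect_equal(cr$upper, theta_hat + half_width, tolerance = 1e-4)
  expect_true(all(cr$profile$chi2 >= cr$chi2_min))

  # limits widen monotonically as the boundary loosens
  cr_loose <- chi2_profile(chi2_fn, theta_hat, grid, boundary = 0.90)
  expect_lt(cr_loose$lower, cr$lower)
  expect_gt(cr_loose$upper, cr$upper)

  # flat profile: both limits unbounded
  flat <- chi2_profile(function(th) chi2_min, theta_hat, grid)
  expect_false(flat$lower_bounded)
  expect_false(flat$upper_bounded)

  expect_error(
    chi2_profile(chi2_fn, theta_hat, grid[grid > theta_hat + half_width]),
    class = "dhalokin_contract_error"
  )
})

test_that("contours on an MM fit bracket the estimate and respect the profile", {
  des <- experiment_design("steady_state",
    enzyme_conc = 0.2,
    substrate_concs = exp(seq(log(100), log(20000), length.out = 12)),
    replicates = 5, noise_sd = 0.02, seed = 4
  )
  ds <- generate_initial_rate_dataset(57, 2350, 0.2, des)
  fit <- fit_michaelis_menten(ds$initial_rates)
  cr <- confidence_contours(fit, "Km", spread = 1.5, n_grid = 25)
  expect_true(cr$lower_bounded && cr$upper_bounded)
  expect_lt(cr$lower, fit$Km)
  expect_gt(cr$upper, fit$Km)
  expect_true(all(cr$profile$chi2 >= cr$chi2_min - 1e-9))
  expect_error(
    confidence_contours(fit, "Km", grid = c(10, 20)),
    class = "dhalokin_contract_error"
  )
})

test_that("ratio error propagation reproduces the published derived errors", {
  ks <- propagate_ratio_error(90, 3, 2.4, 0.1)
  expect_equal(ks$ratio, 37.5)
  expect_equal(ks$se, 2.0, tolerance = 0.02)
  expect_lt(abs(ks$ratio - 38), 2) # printed 38 +- 2

  sp <- propagate_ratio_error(1.1, 0.1, 24, 4)
  expect_equal(sp$ratio, 0.0458, tolerance = 1e-3)
  expect_equal(sp$se, 0.0087, tolerance = 0.02)

  exact <- propagate_ratio_error(6, 0, 3, 0)
  expect_equal(exact$ratio, 2)
  expect_equal(exact$se, 0)

  zero_num <- propagate_ratio_error(0, 0.5, 4, 1)
  expect_equal(zero_num$se, 0.125)
  expect_error(propagate_ratio_error(1, 1, 0, 1), class = "dhalokin_degenerate_error")
})

test_that("Welch comparison matches the closed formulas and stats::t.test", {
  same <- welch_t_test(10, 1, 5, 10, 1, 5)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$significance, "")

  w <- welch_t_test(3.1, 0.1, 3, 12, 4, 3)
  v1 <- 0.1^2
  v2 <- 4^2
  expect_equal(w$t, (3.1 - 12) / sqrt(v1 + v2))
  expect_equal(w$df, (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2))

  # cross-check the sd route against t.test on samples with those moments
  set.seed(2)
  g1 <- rnorm(6)
  g1 <- (g1 - mean(g1)) / sd(g1) * 1.3 + 5
  g2 <- rnorm(8)
  g2 <- (g2 - mean(g2)) / sd(g2) * 2.1 + 7
  ref <- t.test(g1, g2)
  ours <- welch_t_test(5, 1.3, 6, 7, 2.1, 8, dispersion = "sd")
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(welch_t_test(1, 1, 1, 2, 1, 5), class = "dhalokin_contract_error")
})

test_that("reported SEs are calibrated: 2-SE recovery in >= 90% of replicates", {
  # 100 seeded replicates of the steady-state design at 2% noise
  hits <- vapply(1:100, function(s) {
    des <- experiment_design("steady_state",
      enzyme_conc = 0.2,
      substrate_concs = exp(seq(log(100), log(20000), length.out = 12)),
      replicates = 3, noise_sd = 0.02, seed = s
    )
    ds <- generate_initial_rate_dataset(57, 2350, 0.2, des)
    f <- fit_michaelis_menten(ds$initial_rates)
    abs(f$kcat - 57) <= 2 * f$se_kcat
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance expose fit summaries", {
  fix <- bdp_wt_dataset(noise_sd = 0, dt = 0.05, t_end = 0.5)
  f <- global_fit(fix$ds, fix$mech, fix$truth, fix$coeffs,
    free = c("k2", "k3"), n_starts = 1
  )
  td <- tidy(f)
  expect_equal(td$term, c("k2", "k3"))
  expect_equal(nrow(glance(f)), 1)
  expect_true(glance(f)$converged)

  des <- experiment_design("steady_state",
    enzyme_conc = 0.2,
    substrate_concs = c(100, 1000, 10000), replicates = 2,
    noise_sd = 0.02, seed = 1
  )
  mm <- fit_michaelis_menten(
    generate_initial_rate_dataset(57, 2350, 0.2, des)$initial_rates
  )
  expect_equal(tidy(mm)$term, c("kcat", "Km"))
  expect_s3_class(autoplot(mm), "ggplot")
  expect_s3_class(autoplot(f), "ggplot")
})
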