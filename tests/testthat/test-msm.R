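test_that("contact featurization uses a strict distance cutoff", {
  expect_equal(binary_contact_featurize(matrix(7.99), 8)[1, 1], 1L)
  expect_equal(binary_contact_featurize(matrix(8.00), 8)[1, 1], 0L)
  hand <- matrix(c(7, 8, 9, 1), 2, 2) # rows: (7,9), (8,1)
  expect_equal(
    binary_contact_featurize(hand, 8),
    matrix(c(1L, 0L, 0L, 1L), 2, 2)
  )
  expect_true(all(binary_contact_featurize(matrix(50, 3, 4), 8) == 0))
  expect_error(
    binary_contact_featurize(matrix(-1), 8),
    class = "dhalokin_validation_error"
  )
})

test_that("TICA finds the slow coordinate and matches a dense-solver oracle", {
  set.seed(5)
  n <- 2e4
  slow <- as.numeric(arima.sim(list(ar = 0.99), n))
  X <- cbind(slow, matrix(rnorm(n * 3), n, 3))
  tc <- tica(X, lag = 10, n_components = 2)
  w <- tc$components[, 1]
  expect_gt(abs(w[1]) / sqrt(sum(w^2)), 0.95)
  expect_true(all(diff(tc$eigenvalues) <= 1e-12))
  expect_true(all(abs(tc$eigenvalues) <= 1 + 1e-8))

  # pure white noise: no autocorrelation, eigenvalues near zero
  noise <- matrix(rnorm(2e4 * 3), ncol = 3)
  tn <- tica(noise, lag = 5, n_components = 3)
  expect_lt(max(abs(tn$eigenvalues)), 0.1)

  # tiny 2-D series against a brute-force generalized eigensolve
  set.seed(7)
  y <- matrix(rnorm(400), ncol = 2)
  y[, 2] <- y[, 2] + 0.5 * dplyr::lag(y[, 1], default = 0)
  lag <- 3
  tt <- tica(y, lag = lag, n_components = 2)
  yc <- sweep(y, 2, colMeans(y))
  n <- nrow(yc)
  x0 <- yc[1:(n - lag), ]
  xt <- yc[(1 + lag):n, ]
  C0 <- (crossprod(x0) + crossprod(xt)) / (2 * (n - lag))
  Ct <- crossprod(x0, xt) / (n - lag)
  Ct <- (Ct + t(Ct)) / 2
  oracle <- eigen(solve(C0) %*% Ct)
  ord <- order(-Re(oracle$values))
  expect_equal(tt$eigenvalues, Re(oracle$values)[ord], tolerance = 1e-8)
  for (k in 1:2) {
    v1 <- tt$components[, k] / sqrt(sum(tt$components[, k]^2))
    v2 <- Re(oracle$vectors)[, ord[k]]
    v2 <- v2 / sqrt(sum(v2^2))
    expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-8)
  }

  expect_error(tica(y, lag = 1000), class = "dhalokin_contract_error")
})

test_that("microstate clustering separates blobs and is seeded", {
  set.seed(3)
  blob <- rbind(
    matrix(rnorm(500, mean = -4, sd = 0.3), ncol = 2),
    matrix(rnorm(500, mean = 4, sd = 0.3), ncol = 2)
  )
  labels <- rep(1:2, each = 250)
  cl <- cluster_microstates(blob, 2, seed = 1)
  expect_gt(ari(cl$assignments, labels), 0.99)

  cl2 <- cluster_microstates(blob, 2, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)

  # k = n_frames: every frame its own cluster
  small <- matrix(rnorm(10), ncol = 2)
  cl3 <- cluster_microstates(small, 5, seed = 1)
  expect_equal(sort(unique(cl3$assignments)), 1:5)
  expect_error(
    cluster_microstates(small, 6, seed = 1),
    class = "dhalokin_contract_error"
  )
})

test_that("transition estimation matches hand counts and chain statistics", {
  m <- estimate_transition_model(c(0L, 0L, 1L, 1L, 0L), lag = 1)
  expect_equal(unname(unclass(m$count_matrix)), matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(unname(m$transition_matrix), matrix(0.5, 2, 2))
  expect_equal(m$equilibrium_distribution, c(0.5, 0.5))

  T <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2, byrow = TRUE)
  ts <- generate_markov_trajectories(T, 1e5, seed = 21)
  m2 <- estimate_transition_model(ts$state_sequences, lag = 1)
  expect_lt(max(abs(m2$transition_matrix - T)), 0.02)
  expect_lt(max(abs(m2$equilibrium_distribution - c(8 / 9, 1 / 9))), 0.02)
  # rows sum to one, pi is a fixed point
  expect_lt(max(abs(rowSums(m2$transition_matrix) - 1)), 1e-10)
  pi <- m2$equilibrium_distribution
  expect_lt(max(abs(pi %*% m2$transition_matrix - pi)), 1e-8)

  expect_error(
    estimate_transition_model(rep(0L, 10), lag = 1),
    class = "dhalokin_contract_error"
  )
  single <- estimate_transition_model(rep(0L, 10),
    lag = 1,
    allow_single_state = TRUE
  )
  expect_equal(nrow(single$transition_matrix), 1)

  # transient state dropped: model restricted to the largest strongly
  # connected set
  expect_message(
    md <- estimate_transition_model(c(2L, 0L, 1L, 0L, 1L, 0L, 1L), lag = 1),
    "dropped"
  )
  expect_equal(md$dropped_states, 2L)
  expect_equal(md$states, c(0L, 1L))
})

test_that("reversible estimation satisfies detailed balance", {
  set.seed(8)
  for (i in 1:3) {
    n <- sample(2:4, 1)
    T <- matrix(runif(n * n, 0.05, 1), n, n)
    T <- T / rowSums(T)
    ts <- generate_markov_trajectories(T, 2e4, seed = i)
    m <- estimate_transition_model(ts$state_sequences, lag = 1, reversible = TRUE)
    pi <- m$equilibrium_distribution
    flux <- pi * m$transition_matrix
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    expect_lt(max(abs(rowSums(m$transition_matrix) - 1)), 1e-10)
  }
})

test_that("implied timescales follow the eigenvalue closed form and are flat", {
  # crafted sequence with exact counts [[2,1],[1,2]] -> lambda2 = 1/3
  d <- c(0L, 0L, 0L, 1L, 1L, 1L, 0L)
  its <- implied_timescales(d, lags = 1)
  expect_equal(its$eigenvalue[1], 1 / 3, tolerance = 1e-12)
  expect_equal(its$timescale[1], -1 / log(1 / 3), tolerance = 1e-12)

  # Markov chain: t2(tau) flat across lags within sampling error
  T <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  ts <- generate_markov_trajectories(T, 1e5, seed = 31)
  its2 <- implied_timescales(ts$state_sequences, lags = c(1, 2, 5, 10))
  t_ref <- -1 / log(0.9)
  expect_true(all(abs(its2$timescale - t_ref) / t_ref < 0.15))
})

test_that("Chapman-Kolmogorov discrepancy separates Markov from hidden-state", {
  T <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2, byrow = TRUE)
  ts <- generate_markov_trajectories(T, 1e5, seed = 41)
  m <- estimate_transition_model(ts$state_sequences, lag = 1)
  ck <- ck_test(ts$state_sequences, m, factors = c(2L, 5L))
  expect_lt(ck[["2"]]$max_discrepancy, 0.03)

  # deterministic 3-cycle: T(2) = T^2 exactly
  dcyc <- rep(c(0L, 1L, 2L), 300)
  mc <- estimate_transition_model(dcyc, lag = 1)
  ckc <- ck_test(dcyc, mc, factors = 2L)
  expect_equal(ckc[["2"]]$max_discrepancy, 0, tolerance = 1e-12)

  # hidden-state (lumped) chain: states 0 (sticky) and 1 (short-lived) both
  # observe as 0, giving a dwell-time mixture the lumped chain cannot fit
  Th <- matrix(c(
    0.99, 0.00, 0.01,
    0.05, 0.05, 0.90,
    0.00, 0.30, 0.70
  ), 3, 3, byrow = TRUE)
  hid <- generate_markov_trajectories(Th, 5e4, seed = 6)$state_sequences[[1]]
  obs <- c(0L, 0L, 1L)[hid + 1L]
  mo <- estimate_transition_model(obs, lag = 1)
  cko <- ck_test(obs, mo, factors = 2L)
  expect_gt(cko[["2"]]$max_discrepancy, 0.05)

  expect_warning(ck_test(dcyc[1:5], mc, factors = 5L), "skipped")
})

test_that("pathway flux decomposition matches symmetry and path sampling", {
  # A = state 0, channels {1} and {2}, B = state 3
  two_channel <- function(a1, a2) {
    T <- matrix(0, 4, 4)
    T[1, ] <- c(1 - a1 - a2, a1, a2, 0)
    T[2, ] <- c(0.05, 0.85, 0, 0.10)
    T[3, ] <- c(0.05, 0, 0.85, 0.10)
    T[4, ] <- c(0.10, 0.05, 0.05, 0.80)
    T
  }
  # symmetric rates: 0.5 / 0.5
  ms <- exact_model(two_channel(0.1, 0.1))
  fs <- pathway_fractions(ms, 0L, 3L, list(p1 = 1L, p3 = 2L))
  expect_equal(fs$fraction, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sum(fs$fraction), 1)

  # single channel: fraction 1
  T1 <- matrix(c(
    0.8, 0.2, 0,
    0.1, 0.8, 0.1,
    0.1, 0.1, 0.8
  ), 3, 3, byrow = TRUE)
  f1 <- pathway_fractions(exact_model(T1), 0L, 2L, list(only = 1L))
  expect_equal(f1$fraction, 1)

  # asymmetric chain versus Monte-Carlo first-passage path sampling
  Ta <- two_channel(0.15, 0.05)
  ma <- exact_model(Ta)
  fa <- pathway_fractions(ma, 0L, 3L, list(p1 = 1L, p3 = 2L))

  set.seed(17)
  long <- generate_markov_trajectories(Ta, 4e5, seed = 17)$state_sequences[[1]]
  # reactive A->B segments of the stationary path ensemble, classified by
  # the channel visited last before absorption
  n_p1 <- 0L
  n_p3 <- 0L
  inside <- FALSE
  last_channel <- NA_integer_
  for (s in long) {
    if (s == 0L) {
      inside <- TRUE
      last_channel <- NA_integer_
    } else if (inside && (s == 1L || s == 2L)) {
      last_channel <- s
    } else if (s == 3L) {
      if (inside && !is.na(last_channel)) {
        if (last_channel == 1L) n_p1 <- n_p1 + 1L else n_p3 <- n_p3 + 1L
      }
      inside <- FALSE
    }
  }
  n_paths <- n_p1 + n_p3
  p_hat <- n_p1 / n_paths
  se <- sqrt(p_hat * (1 - p_hat) / n_paths)
  expect_lt(abs(fa$fraction[fa$channel == "p1"] - p_hat), 3 * se)

  expect_error(
    pathway_fractions(ma, 0L, 3L, list(p1 = 1L)),
    class = "dhalokin_contract_error"
  )
  expect_error(
    pathway_fractions(ma, 0L, 0L, list(p1 = 1L, p3 = 2L)),
    class = "dhalokin_contract_error"
  )
})

test_that("NAC classification applies inclusive bounds exactly", {
  crit <- nac_criteria()
  g <- tibble::tibble(
    distance_A = c(3.41, 3.41, 3.42, 3.41, 10, 2.9, 3.0),
    angle_deg = c(170, 157, 170, 180, 170, 156.99, 90)
  )
  cls <- classify_nac(g, crit)
  expect_equal(cls$is_nac, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(nac_fraction(cls), 3 / 7)

  expect_error(
    classify_nac(tibble::tibble(distance_A = 3, angle_deg = 200)),
    class = "dhalokin_validation_error"
  )
  expect_error(
    classify_nac(tibble::tibble(distance_A = 0, angle_deg = 100)),
    class = "dhalokin_validation_error"
  )
  expect_error(nac_criteria(max_distance = -1), class = "dhalokin_config_error")
})

test_that("macrostate populations sum stationary probabilities", {
  T <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2, byrow = TRUE)
  m <- exact_model(T)
  expect_equal(macrostate_population(m, 0L), 8 / 9, tolerance = 1e-10)
  expect_equal(macrostate_population(m, c(0L, 1L)), 1)
  expect_equal(
    macrostate_population(m, 0L) + macrostate_population(m, 1L), 1
  )
  # conditional population within a reference set
  T3 <- matrix(c(
    0.8, 0.1, 0.1,
    0.1, 0.8, 0.1,
    0.1, 0.1, 0.8
  ), 3, 3, byrow = TRUE)
  m3 <- exact_model(T3)
  expect_equal(macrostate_population(m3, 0L, within = c(0L, 1L)), 0.5,
    tolerance = 1e-10
  )
  expect_error(macrostate_population(m, integer(0)), class = "dhalokin_contract_error")
  expect_error(macrostate_population(m, 5L), class = "dhalokin_contract_error")
})

test_that("full pipeline recovers the slowest timescale of a hidden 3-state chain", {
  # 3-state chain with distinct Gaussian emissions; featurize -> TICA ->
  # cluster -> estimate recovers the slowest implied timescale
  Th <- matrix(c(
    0.98, 0.01, 0.01,
    0.02, 0.96, 0.02,
    0.01, 0.01, 0.98
  ), 3, 3, byrow = TRUE)
  ev <- sort(Re(eigen(Th)$values), decreasing = TRUE)
  t2_true <- -1 / log(ev[2])
  mu <- rbind(c(0, 0, 0, 0), c(4, 0, 2, 0), c(0, 4, 0, 2))
  ts <- generate_markov_trajectories(Th, 1e5,
    emission_spec = list(means = mu, sd = 0.8), seed = 13
  )
  tc <- tica(ts$features[[1]], lag = 5, n_components = 2)
  cl <- cluster_microstates(tc$projections, 6, seed = 13)
  m <- estimate_transition_model(cl$assignments - 1L, lag = 5)
  lam2 <- sort(Re(eigen(m$transition_matrix)$values), decreasing = TRUE)[2]
  t2_est <- -5 / log(lam2)
  expect_lt(abs(t2_est - t2_true) / t2_true, 0.15)
})
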