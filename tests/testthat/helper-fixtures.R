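# Shared fixtures and independent oracles, all built in code.

# explicit fixed-step Euler integrator for the four-step scheme --
# deliberately naive, used only as an independent oracle for the ODE path
euler_four_step <- function(k1, km1, k2, k3, k4, km4, E0, S0, t_out, dt = 1e-4) {
  y <- c(E = E0, S = S0, ES = 0, EI = 0, EP = 0, P = 0)
  out <- matrix(NA_real_, length(t_out), 6,
    dimnames = list(NULL, names(y))
  )
  t <- 0
  i <- 1
  while (i <= length(t_out)) {
    while (t_out[i] <= t + dt / 2) {
      out[i, ] <- y
      i <- i + 1
      if (i > length(t_out)) {
        return(out)
      }
    }
    vb <- k1 * y["E"] * y["S"] - km1 * y["ES"]
    v2 <- k2 * y["ES"]
    v3 <- k3 * y["EI"]
    v4 <- k4 * y["EP"] - km4 * y["E"] * y["P"]
    y <- y + dt * c(-vb + v4, -vb, vb - v2, v2 - v3, v3 - v4, v4)
    t <- t + dt
  }
  out
}

# adjusted Rand index between two hard partitions
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# wrap an exact transition matrix as a transition_model (for oracles that
# need the model container without estimation noise)
exact_model <- function(T, lag = 1L) {
  structure(
    list(
      count_matrix = T * 0,
      transition_matrix = T,
      equilibrium_distribution = dhalokin:::stationary_distribution(T),
      lag = as.integer(lag),
      states = seq_len(nrow(T)) - 1L,
      dropped_states = integer(0),
      reversible = FALSE
    ),
    class = "transition_model"
  )
}

# small noiseless stopped-flow dataset around the BDP/LinBwt parameter set
bdp_wt_dataset <- function(noise_sd = 0, seed = 1, dt = 0.01, t_end = 1.5,
                           concs = c(2, 6, 10)) {
  mech <- build_mechanism("four_step")
  truth <- rate_parameters(k1 = 2.4, k_minus1 = 90, k2 = 5.9, k3 = 20, k4 = 20)
  co <- signal_coefficients("V1_ex500", f = 1, a = 2, b = 6)
  des <- experiment_design("stopped_flow",
    enzyme_conc = 30,
    substrate_concs = concs,
    time_grid = seq(0, t_end, by = dt),
    noise_sd = noise_sd, noise_relative = noise_sd > 0, seed = seed
  )
  ds <- generate_stopped_flow_dataset(mech, truth, co, des)
  if (noise_sd == 0) ds$traces$sigma <- 0.01
  list(ds = ds, mech = mech, truth = truth, coeffs = co)
}
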