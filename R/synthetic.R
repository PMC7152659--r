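#' Experiment design for synthetic kinetic datasets
#'
#' Describes either a stopped-flow experiment (one fluorescence trace per
#' substrate concentration on a common time grid) or a steady-state
#' initial-rate experiment (replicated initial velocities across a substrate
#' series).
#'
#' @param mode `"stopped_flow"` or `"steady_state"`.
#' @param enzyme_conc Enzyme concentration per trace/series (uM).
#' @param substrate_concs Substrate concentrations (uM), non-empty, all > 0.
#' @param time_grid Time grid (s) for stopped-flow traces.
#' @param replicates Replicates per concentration (steady state), >= 1.
#' @param noise_sd Gaussian noise level; either an absolute sd in signal
#'   units, or a fraction of trace amplitude when `noise_relative = TRUE`.
#' @param noise_relative Interpret `noise_sd` as fraction of amplitude.
#' @param dead_time_s Stopped-flow dead time; samples with `t < dead_time_s`
#'   are discarded (instrument mixing time, default 1 ms).
#' @param conc_jitter Optional fractional jitter (e.g. 0.1 for +-10%) applied
#'   to nominal concentrations to exercise the fitter's concentration
#'   adjustment; true values are recorded in the dataset metadata.
#' @param seed Integer seed; same seed gives a bit-identical dataset.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(mode = c("stopped_flow", "steady_state"),
                              enzyme_conc, substrate_concs,
                              time_grid = NULL, replicates = 1L,
                              noise_sd = 0.01, noise_relative = TRUE,
                              dead_time_s = 0.001, conc_jitter = 0,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (!length(substrate_concs) || any(substrate_concs <= 0)) {
    abort("substrate_concs must be non-empty and > 0",
      class = "dhalokin_config_error"
    )
  }
  if (replicates < 1) abort("replicates must be >= 1", class = "dhalokin_config_error")
  if (mode == "stopped_flow" && is.null(time_grid)) {
    abort("stopped_flow design requires a time_grid", class = "dhalokin_config_error")
  }
  structure(
    list(
      mode = mode, enzyme_conc = enzyme_conc,
      substrate_concs = substrate_concs, time_grid = time_grid,
      replicates = as.integer(replicates), noise_sd = noise_sd,
      noise_relative = noise_relative, dead_time_s = dead_time_s,
      conc_jitter = conc_jitter, seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

new_kinetic_dataset <- function(traces, initial_rates, truth) {
  structure(
    list(traces = traces, initial_rates = initial_rates, truth = truth),
    class = "kinetic_dataset"
  )
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat("<kinetic_dataset>\n")
  if (nrow(x$traces)) {
    cat(
      "  traces:        ", dplyr::n_distinct(x$traces$trace_id),
      " (", nrow(x$traces), " points)\n",
      sep = ""
    )
  }
  if (nrow(x$initial_rates)) {
    cat("  initial rates: ", nrow(x$initial_rates), " points\n", sep = "")
  }
  if (!is.null(x$truth$seed)) cat("  seed:          ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

# run fn under a local RNG state seeded with `seed`
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic stopped-flow fluorescence dataset
#'
#' Simulates one trace per substrate concentration with
#' [simulate_timecourse()], maps species to a fluorescence signal via the
#' observable model, and adds i.i.d. Gaussian noise. The per-point `sigma`
#' column records the true noise sd, mirroring an instrument with known
#' measurement error. Samples before the dead time are discarded.
#'
#' @param mechanism,rates Mechanism and ground-truth rate constants.
#' @param coeffs A [signal_coefficients()] object, or a species name for an
#'   identity observable (substrates without a fluorogenic model).
#' @param design An [experiment_design()] with `mode = "stopped_flow"`.
#' @return A `"kinetic_dataset"`: `$traces` is a tibble with columns
#'   `trace_id`, `S0_uM`, `E0_uM`, `time_s`, `signal`, `sigma`; `$truth`
#'   records the generating parameters for recovery scoring.
#' @export
generate_stopped_flow_dataset <- function(mechanism, rates, coeffs, design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$mode != "stopped_flow") {
    abort("design mode must be stopped_flow", class = "dhalokin_config_error")
  }
  if (design$noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "dhalokin_config_error")
  }
  with_seed(design$seed, function() {
    true_S0 <- design$substrate_concs
    true_E0 <- rep(design$enzyme_conc, length(true_S0))
    if (design$conc_jitter > 0) {
      true_S0 <- true_S0 * runif(length(true_S0), 1 - design$conc_jitter, 1 + design$conc_jitter)
      true_E0 <- true_E0 * runif(length(true_E0), 1 - design$conc_jitter, 1 + design$conc_jitter)
    }
    keep <- design$time_grid >= design$dead_time_s
    traces <- purrr::map_dfr(seq_along(true_S0), function(i) {
      st <- simulate_timecourse(
        mechanism, rates,
        E0 = true_E0[i], S0 = true_S0[i],
        times = design$time_grid
      )
      sig <- apply_observable(st, coeffs)[keep, ]
      sdv <- if (design$noise_relative) {
        design$noise_sd * diff(range(sig$signal))
      } else {
        design$noise_sd
      }
      sdv <- max(sdv, .Machine$double.eps)
      tibble(
        trace_id = i,
        S0_uM = design$substrate_concs[i],
        E0_uM = design$enzyme_conc,
        time_s = sig$time_s,
        signal = sig$signal + rnorm(nrow(sig), 0, sdv),
        sigma = sdv
      )
    })
    new_kinetic_dataset(
      traces = traces,
      initial_rates = empty_initial_rates(),
      truth = list(
        rates = rates, coeffs = coeffs, mechanism = mechanism,
        true_S0 = true_S0, true_E0 = true_E0, seed = design$seed,
        design = design
      )
    )
  })
}

#' Generate a synthetic Michaelis-Menten initial-rate dataset
#'
#' Initial velocities are drawn from `v0 = kcat * E0 * S / (Km + S)` plus
#' Gaussian noise with sd `noise_sd` (absolute, or a fraction of the
#' saturating rate `kcat * E0` when `noise_relative`).
#'
#' @param kcat,Km Generating steady-state constants (1/s, uM); `Km > 0`.
#' @param E0 Enzyme concentration (uM).
#' @param design An [experiment_design()] with `mode = "steady_state"`.
#' @return A `"kinetic_dataset"` with `$initial_rates`: tibble columns
#'   `S_uM`, `E_uM`, `replicate`, `v_uM_per_s`, `sigma`.
#' @export
generate_initial_rate_dataset <- function(kcat, Km, E0, design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$mode != "steady_state") {
    abort("design mode must be steady_state", class = "dhalokin_config_error")
  }
  if (is.na(Km) || Km <= 0) abort("Km must be > 0", class = "dhalokin_config_error")
  with_seed(design$seed, function() {
    grid <- tidyr::expand_grid(
      S_uM = design$substrate_concs,
      replicate = seq_len(design$replicates)
    )
    v_true <- kcat * E0 * grid$S_uM / (Km + grid$S_uM)
    sdv <- if (design$noise_relative) design$noise_sd * kcat * E0 else design$noise_sd
    sdv <- max(sdv, .Machine$double.eps)
    rates_tb <- tibble(
      S_uM = grid$S_uM,
      E_uM = E0,
      replicate = grid$replicate,
      v_uM_per_s = v_true + rnorm(nrow(grid), 0, sdv),
      sigma = sdv
    )
    new_kinetic_dataset(
      traces = empty_traces(),
      initial_rates = rates_tb,
      truth = list(kcat = kcat, Km = Km, E0 = E0, seed = design$seed, design = design)
    )
  })
}

empty_traces <- function() {
  tibble(
    trace_id = integer(), S0_uM = numeric(), E0_uM = numeric(),
    time_s = numeric(), signal = numeric(), sigma = numeric()
  )
}

empty_initial_rates <- function() {
  tibble(
    S_uM = numeric(), E_uM = numeric(), replicate = integer(),
    v_uM_per_s = numeric(), sigma = numeric()
  )
}

#' Sample discrete trajectories from a known Markov chain
#'
#' Draws `n_traj` state sequences of length `n_steps` from the row-stochastic
#' transition matrix `T`, each started from the uniform distribution over
#' states. Optionally attaches per-frame feature vectors drawn from
#' state-conditioned spherical Gaussians (a minimal emission model giving
#' TICA/clustering something to recover without MD realism).
#'
#' @param transition_matrix Row-stochastic matrix (rows sum to 1 within
#'   1e-12).
#' @param n_steps Steps per trajectory, >= 2.
#' @param n_traj Number of trajectories.
#' @param emission_spec Optional list with `means` (n_states x d matrix of
#'   state centres) and `sd` (scalar emission sd).
#' @param seed Integer seed.
#' @return An object of class `"trajectory_set"`: list with
#'   `transition_matrix`, `state_sequences` (list of integer vectors, states
#'   in `0:(n-1)`), `features` (list of matrices or `NULL`), `seed`.
#' @export
generate_markov_trajectories <- function(transition_matrix, n_steps, n_traj = 1L,
                                         emission_spec = NULL, seed = 1L) {
  T <- as.matrix(transition_matrix)
  check_stochastic(T)
  if (n_steps < 2) abort("n_steps must be >= 2", class = "dhalokin_config_error")
  n <- nrow(T)
  with_seed(seed, function() {
    seqs <- purrr::map(seq_len(n_traj), function(j) {
      s <- integer(n_steps)
      s[1] <- sample.int(n, 1)
      for (t in 2:n_steps) s[t] <- sample.int(n, 1, prob = T[s[t - 1], ])
      s - 1L
    })
    feats <- NULL
    if (!is.null(emission_spec)) {
      mu <- as.matrix(emission_spec$means)
      if (nrow(mu) != n) {
        abort("emission_spec$means must have one row per state",
          class = "dhalokin_config_error"
        )
      }
      sdv <- emission_spec$sd %||% 1
      feats <- purrr::map(seqs, function(s) {
        mu[s + 1L, , drop = FALSE] +
          matrix(rnorm(length(s) * ncol(mu), 0, sdv), length(s), ncol(mu))
      })
    }
    structure(
      list(
        transition_matrix = T, state_sequences = seqs,
        features = feats, seed = as.integer(seed)
      ),
      class = "trajectory_set"
    )
  })
}

check_stochastic <- function(T, tol = 1e-12) {
  if (!is.matrix(T) || nrow(T) != ncol(T) || any(T < 0)) {
    abort("transition matrix must be square and nonnegative",
      class = "dhalokin_validation_error"
    )
  }
  rs <- rowSums(T)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    abort(
      paste0(
        "transition matrix rows must sum to 1; offending row(s): ",
        paste(bad, collapse = ", ")
      ),
      class = "dhalokin_validation_error"
    )
  }
  invisible(T)
}

#' Generate toy near-attack-conformer geometry frames
#'
#' Emits per-frame reaction geometries (nucleophile-carbon distance, in
#' Angstrom, and nucleophile-carbon-halide angle, in degrees) with a known
#' fraction of frames inside the near-attack-conformer (NAC) window
#' (distance <= 3.41 A, angle in [157, 180] degrees). NAC frames are drawn
#' uniformly inside the window (distance in [2.8, 3.41]); non-NAC frames
#' uniformly outside it. The generating label is recorded for scoring the
#' classifier.
#'
#' @param n_frames Number of frames.
#' @param fraction_nac Fraction of NAC frames in [0, 1].
#' @param jitter Unused margin kept for interface stability; boundary frames
#'   are generated strictly inside/outside the window.
#' @param seed Integer seed.
#' @return A tibble with columns `frame`, `distance_A`, `angle_deg`,
#'   `is_nac_true`.
#' @export
generate_nac_geometries <- function(n_frames, fraction_nac, jitter = 0, seed = 1L) {
  if (fraction_nac < 0 || fraction_nac > 1) {
    abort("fraction_nac must be in [0, 1]", class = "dhalokin_config_error")
  }
  with_seed(seed, function() {
    is_nac <- runif(n_frames) < fraction_nac
    n_in <- sum(is_nac)
    dist <- angle <- numeric(n_frames)
    dist[is_nac] <- runif(n_in, 2.8, 3.41)
    angle[is_nac] <- runif(n_in, 157, 180)
    # non-NAC: either too far, or close but mis-aligned
    n_out <- n_frames - n_in
    far <- runif(n_out) < 0.5
    d_out <- ifelse(far, runif(n_out, 3.6, 8), runif(n_out, 2.8, 3.41))
    a_out <- ifelse(far, runif(n_out, 0, 180), runif(n_out, 60, 150))
    dist[!is_nac] <- d_out
    angle[!is_nac] <- a_out
    tibble(
      frame = seq_len(n_frames),
      distance_A = dist,
      angle_deg = angle,
      is_nac_true = is_nac
    )
  })
}
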