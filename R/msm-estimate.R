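as_dtraj_list <- function(dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  purrr::map(dtrajs, function(d) {
    d <- as.integer(d)
    if (any(d < 0)) {
      abort("state labels must be >= 0", class = "dhalokin_validation_error")
    }
    d
  })
}

count_transitions <- function(dtrajs, lag, n_states) {
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs) {
    n <- length(d)
    if (n <= lag) next
    from <- d[1:(n - lag)] + 1L
    to <- d[(1 + lag):n] + 1L
    idx <- cbind(from, to)
    tab <- table(factor(from, levels = 1:n_states), factor(to, levels = 1:n_states))
    C <- C + unclass(tab)
  }
  C
}

stationary_distribution <- function(T) {
  eg <- eigen(t(T))
  i <- which.min(abs(eg$values - 1))
  v <- Re(eg$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Detailed-balance maximum-likelihood estimator: fixed-point iteration on the
# unnormalized symmetric flux matrix x_ij (standard MSM reversible MLE).
reversible_mle <- function(C, tol = 1e-12, max_iter = 10000) {
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol) break
  }
  T <- x / rowSums(x)
  pi <- rowSums(x) / sum(x)
  list(T = T, pi = pi)
}

#' Estimate a Markov state model transition matrix
#'
#' Counts transitions at the given lag with a sliding window, restricts to
#' the largest strongly connected set of states, and estimates a
#' row-stochastic transition matrix: simple row normalization of the count
#' matrix (default), or a reversible maximum-likelihood estimate satisfying
#' detailed balance. The equilibrium distribution is the stationary left
#' eigenvector of the transition matrix.
#'
#' @param dtrajs Integer vector or list of vectors; state labels are
#'   0-based.
#' @param lag Lag in frames, >= 1.
#' @param reversible Use the detailed-balance MLE.
#' @param allow_single_state Permit a degenerate single-state model instead
#'   of erroring on a constant trajectory.
#' @return An object of class `"transition_model"`: `count_matrix`,
#'   `transition_matrix`, `equilibrium_distribution`, `lag`, `states`
#'   (0-based labels retained in the connected set), `dropped_states`,
#'   `reversible`.
#' @export
#' @examples
#' estimate_transition_model(c(0L, 0L, 1L, 1L, 0L), lag = 1)
estimate_transition_model <- function(dtrajs, lag = 1L, reversible = FALSE,
                                      allow_single_state = FALSE) {
  dtrajs <- as_dtraj_list(dtrajs)
  if (lag < 1) abort("lag must be >= 1", class = "dhalokin_contract_error")
  n_states <- max(purrr::map_int(dtrajs, ~ max(.x))) + 1L
  C <- count_transitions(dtrajs, lag, n_states)
  if (sum(C) == 0) {
    abort("no transitions observed at this lag", class = "dhalokin_contract_error")
  }

  # largest strongly connected component of the transition graph
  g <- igraph::graph_from_adjacency_matrix((C > 0) + 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  keep_comp <- which.max(tabulate(comp$membership))
  keep <- sort(unname(which(comp$membership == keep_comp)))
  dropped <- setdiff(seq_len(n_states), keep)
  if (length(dropped)) {
    message(
      "estimate_transition_model: dropped ", length(dropped),
      " state(s) outside the largest connected set"
    )
  }
  C <- C[keep, keep, drop = FALSE]
  if (nrow(C) == 1 && !allow_single_state) {
    abort("degenerate chain: a single connected state (set allow_single_state = TRUE to accept)",
      class = "dhalokin_contract_error"
    )
  }

  if (reversible && nrow(C) > 1) {
    est <- reversible_mle(C)
    T <- est$T
    pi <- est$pi
  } else {
    T <- C / rowSums(C)
    pi <- stationary_distribution(T)
  }

  structure(
    list(
      count_matrix = C,
      transition_matrix = T,
      equilibrium_distribution = pi,
      lag = as.integer(lag),
      states = keep - 1L,
      dropped_states = dropped - 1L,
      reversible = reversible
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", nrow(x$transition_matrix), " states, lag ",
    x$lag, if (x$reversible) ", reversible", "\n",
    sep = ""
  )
  cat(
    "  pi: ", paste(signif(x$equilibrium_distribution, 3), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Implied relaxation timescales across lag times
#'
#' For each lag, estimates a transition matrix and converts its eigenvalues
#' to implied timescales `t_i(tau) = -tau / log(lambda_i(tau))` (eigenvalues
#' below 1 in magnitude; the stationary eigenvalue is skipped, and an
#' eigenvalue within numerical reach of 1 reports an infinite timescale).
#' Timescale curves flat in `tau` indicate Markovian behaviour at that lag.
#'
#' @inheritParams estimate_transition_model
#' @param lags Integer vector of lags to scan.
#' @param n_timescales How many timescales to report (default all).
#' @return A tibble with columns `lag`, `index`, `eigenvalue`, `timescale`.
#' @export
implied_timescales <- function(dtrajs, lags, reversible = FALSE,
                               n_timescales = NULL) {
  dtrajs <- as_dtraj_list(dtrajs)
  purrr::map_dfr(lags, function(tau) {
    m <- estimate_transition_model(dtrajs, lag = tau, reversible = reversible)
    ev <- eigen(m$transition_matrix)$values
    if (reversible && any(abs(Im(ev)) > 1e-8)) {
      abort("complex eigenvalues beyond tolerance in reversible mode",
        class = "dhalokin_numeric_error"
      )
    }
    ev <- Re(ev)[order(-abs(Re(ev)))]
    ev <- ev[-1] # drop the stationary eigenvalue
    if (!is.null(n_timescales)) ev <- ev[seq_len(min(n_timescales, length(ev)))]
    ts <- ifelse(abs(ev) >= 1 - 1e-12, Inf,
      ifelse(ev <= 0, NA_real_, -tau / log(ev))
    )
    tibble(
      lag = tau, index = seq_along(ev) + 1L,
      eigenvalue = ev, timescale = ts
    )
  })
}

#' Chapman-Kolmogorov test
#'
#' Compares the model prediction `T(tau)^k` against a transition matrix
#' re-estimated directly at the longer lag `k * tau`, for each factor `k`.
#' For a Markovian process the two agree up to sampling error; systematic
#' discrepancy indicates memory beyond the lag.
#'
#' @param dtrajs Discrete trajectories (0-based labels).
#' @param model A `"transition_model"` estimated at the base lag.
#' @param factors Integer factors `k >= 2`.
#' @return A list of class `"ck_test"`: one element per factor with
#'   `factor`, `predicted`, `estimated`, `max_discrepancy`; factors with
#'   insufficient data are skipped with a warning.
#' @export
ck_test <- function(dtrajs, model, factors = c(2L, 5L)) {
  stopifnot(inherits(model, "transition_model"))
  dtrajs <- as_dtraj_list(dtrajs)
  maxlen <- max(purrr::map_int(dtrajs, length))
  out <- list()
  for (k in factors) {
    if (k < 2) abort("factors must be >= 2", class = "dhalokin_contract_error")
    if (k * model$lag >= maxlen) {
      warn(paste0("ck_test: factor ", k, " skipped (k*lag exceeds trajectory length)"))
      next
    }
    direct <- tryCatch(
      estimate_transition_model(dtrajs,
        lag = k * model$lag,
        reversible = model$reversible
      ),
      error = function(e) NULL
    )
    if (is.null(direct) ||
      !identical(direct$states, model$states)) {
      warn(paste0("ck_test: factor ", k, " skipped (insufficient data at k*lag)"))
      next
    }
    Tk <- matpow(model$transition_matrix, k)
    disc <- max(abs(Tk - direct$transition_matrix))
    out[[as.character(k)]] <- list(
      factor = k, predicted = Tk,
      estimated = direct$transition_matrix,
      max_discrepancy = disc
    )
  }
  structure(out, class = "ck_test")
}

matpow <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}

#' Equilibrium population of a macrostate
#'
#' Sums the stationary distribution over a set of microstates. The
#' conditional form reports the fraction that `state_set` carries within a
#' reference set (e.g. a conformation's share of all bound states).
#'
#' @param model A `"transition_model"`.
#' @param state_set Integer vector of 0-based state labels (must be states
#'   of the model).
#' @param within Optional reference set for a conditional population.
#' @return A single probability.
#' @export
macrostate_population <- function(model, state_set, within = NULL) {
  stopifnot(inherits(model, "transition_model"))
  if (!length(state_set)) {
    abort("state_set must be non-empty", class = "dhalokin_contract_error")
  }
  idx <- match(state_set, model$states)
  if (anyNA(idx)) {
    abort("state_set contains states not in the model",
      class = "dhalokin_contract_error"
    )
  }
  p <- sum(model$equilibrium_distribution[idx])
  if (!is.null(within)) {
    widx <- match(within, model$states)
    if (anyNA(widx)) {
      abort("within contains states not in the model",
        class = "dhalokin_contract_error"
      )
    }
    p <- p / sum(model$equilibrium_distribution[widx])
  }
  p
}
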