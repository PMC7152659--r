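# Transition-path theory on a discrete Markov chain: committors, reactive
# flux, and decomposition of source->sink flux among transport channels
# (access tunnels).

forward_committor <- function(T, source_idx, sink_idx) {
  n <- nrow(T)
  q <- numeric(n)
  q[sink_idx] <- 1
  inter <- setdiff(seq_len(n), c(source_idx, sink_idx))
  if (length(inter)) {
    A <- diag(length(inter)) - T[inter, inter, drop = FALSE]
    b <- T[inter, sink_idx, drop = FALSE] %*% rep(1, length(sink_idx))
    q[inter] <- solve(A, b)
  }
  q
}

#' Decompose source-to-sink reactive flux among transport channels
#'
#' Computes the committor-based reactive flux (transition-path theory) of a
#' Markov state model from a source macrostate (e.g. ligand in bulk solvent)
#' to a sink macrostate (e.g. ligand bound in the active site), and
#' partitions it among channels — disjoint groups of intermediate states
#' representing distinct transport pathways such as the main p1 tunnel and
#' the auxiliary p3 tunnel.
#'
#' The forward committor `q+` solves the absorbing linear system of the
#' chain; the backward committor uses the time-reversed chain
#' `T~_ij = pi_j T_ji / pi_i`. The reactive flux along an edge is
#' `f_ij = pi_i q-_i T_ij q+_j` (i != j), and net fluxes
#' `F_ij = max(f_ij - f_ji, 0)` are decomposed: each channel's share is the
#' net flux it delivers into the sink, divided by the total reactive flux
#' out of the source. Every intermediate state must be mapped to exactly one
#' channel; direct source-to-sink flux, if present, is reported under
#' `"direct"`.
#'
#' @param model A `"transition_model"`.
#' @param source_states,sink_states Disjoint, non-empty 0-based state sets.
#' @param channel_map Named list mapping channel name -> integer vector of
#'   0-based intermediate states; together the channels must partition the
#'   intermediate states.
#' @return A tibble with columns `channel`, `flux`, `fraction` (fractions
#'   sum to 1 over the source->sink reactive flux).
#' @export
pathway_fractions <- function(model, source_states, sink_states, channel_map) {
  stopifnot(inherits(model, "transition_model"))
  if (!length(source_states) || !length(sink_states)) {
    abort("source and sink must be non-empty", class = "dhalokin_contract_error")
  }
  if (length(intersect(source_states, sink_states))) {
    abort("source and sink must be disjoint", class = "dhalokin_contract_error")
  }
  A <- match(source_states, model$states)
  B <- match(sink_states, model$states)
  if (anyNA(A) || anyNA(B)) {
    abort("source/sink contain states not in the model",
      class = "dhalokin_contract_error"
    )
  }
  T <- model$transition_matrix
  n <- nrow(T)
  inter <- setdiff(seq_len(n), c(A, B))
  inter_labels <- model$states[inter]
  mapped <- unlist(channel_map, use.names = FALSE)
  if (length(setdiff(inter_labels, mapped)) || anyDuplicated(mapped)) {
    abort("channel_map must assign every intermediate state to exactly one channel",
      class = "dhalokin_contract_error"
    )
  }

  pi <- model$equilibrium_distribution
  qf <- forward_committor(T, A, B)
  if (all(qf[inter] == 0) && length(inter)) {
    abort("sink unreachable from source through the intermediate states",
      class = "dhalokin_contract_error"
    )
  }
  # backward committor via the time-reversed chain
  Trev <- t(T) * outer(1 / pi, pi)
  qb <- forward_committor(Trev, B, A) # prob. of having come from A

  f <- outer(pi * qb, qf) * T
  diag(f) <- 0
  Fnet <- pmax(f - t(f), 0)

  total <- sum(Fnet[A, , drop = FALSE])
  if (total <= 0) {
    abort("no reactive flux from source to sink", class = "dhalokin_contract_error")
  }

  fluxes <- purrr::imap_dbl(channel_map, function(states, nm) {
    idx <- match(intersect(states, inter_labels), model$states)
    if (!length(idx)) return(0)
    sum(Fnet[idx, B, drop = FALSE])
  })
  direct <- sum(Fnet[A, B, drop = FALSE])
  if (direct > 1e-12 * total) {
    fluxes <- c(fluxes, direct = direct)
  }
  tibble(
    channel = names(fluxes),
    flux = unname(fluxes),
    fraction = unname(fluxes) / sum(fluxes)
  )
}
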