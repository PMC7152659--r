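# Tabular I/O. All kinetic CSVs use uM and s; '#'-prefixed header lines
# carry metadata (units, seed, generating parameters).

write_csv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_with_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  structure(as_tibble(df), meta = meta)
}

#' Read and write stopped-flow trace CSV files
#'
#' Traces are stored one file per dataset with columns
#' `trace_id,S0_uM,E0_uM,time_s,signal,sigma`; metadata (units, seed,
#' generating parameters) travels in `#`-prefixed header lines.
#'
#' @param traces Trace tibble (see [generate_stopped_flow_dataset()]).
#' @param path File path.
#' @param meta Named list of metadata entries.
#' @return `read_trace_csv` returns the tibble with metadata in
#'   `attr(, "meta")`; the writer returns the path invisibly.
#' @export
write_trace_csv <- function(traces, path, meta = list()) {
  meta <- c(list(units = "time_s [s], signal [a.u.], concentrations [uM]"), meta)
  write_csv_with_meta(traces, path, meta)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  read_csv_with_meta(path)
}

#' Read and write initial-rate CSV files
#'
#' Columns `S_uM,E_uM,v_uM_per_s,sigma` (plus `replicate`).
#'
#' @inheritParams write_trace_csv
#' @param initial_rates Initial-rate tibble.
#' @export
write_initial_rate_csv <- function(initial_rates, path, meta = list()) {
  meta <- c(list(units = "S_uM [uM], E_uM [uM], v_uM_per_s [uM/s]"), meta)
  write_csv_with_meta(initial_rates, path, meta)
}

#' @rdname write_initial_rate_csv
#' @export
read_initial_rate_csv <- function(path) {
  read_csv_with_meta(path)
}

#' Write a species trajectory CSV
#'
#' Standard header `time_s,E,S,ES,EI,EP,P` (uM).
#'
#' @param states Output of [simulate_timecourse()].
#' @param path File path.
#' @param meta Named list of metadata entries.
#' @export
write_trajectory_csv <- function(states, path, meta = list()) {
  write_csv_with_meta(
    states[, c("time_s", "E", "S", "ES", "EI", "EP", "P")],
    path, meta
  )
}

#' Read or write a run configuration
#'
#' Configurations are YAML with blocks `mechanism` (scheme,
#' rapid_equilibrium, rate constants, Ks), `observable` (channel and
#' factors), `design`, `fit` (free parameters, restarts), `msm` (cutoff,
#' lags, clusters) and a top-level `seed`. Units are fixed (uM, s) and not
#' part of the config. Configs round-trip losslessly through
#' `write_run_config()` / `read_run_config()`.
#'
#' @param config Named list.
#' @param path File path.
#' @return `read_run_config` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "dhalokin_config_error")
  }
  yaml::read_yaml(path)
}

config_mechanism <- function(block) {
  if (is.null(block$scheme)) {
    abort("config: mechanism block requires 'scheme'",
      class = "dhalokin_config_error"
    )
  }
  build_mechanism(block$scheme, isTRUE(block$rapid_equilibrium))
}

config_rates <- function(block) {
  get_num <- function(nm) if (is.null(block[[nm]])) NA_real_ else as.numeric(block[[nm]])
  rate_parameters(
    k1 = get_num("k1"), k_minus1 = get_num("k_minus1"),
    k2 = get_num("k2"), k3 = get_num("k3"), k4 = get_num("k4"),
    k_minus4 = if (is.null(block$k_minus4)) 0 else as.numeric(block$k_minus4),
    Ks = get_num("Ks")
  )
}

config_observable <- function(block) {
  if (is.null(block)) {
    return(NULL)
  }
  if (!is.null(block$species)) {
    return(block$species)
  }
  do.call(signal_coefficients, block)
}
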