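# End-to-end pipeline runners. These are the programmatic equivalents of a
# command-line front end: each takes a config (path or list), writes its
# artifacts under an output directory, and returns the report invisibly.
# Every artifact records the seed, so any output is reproducible bit-for-bit
# from its config.

resolve_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) {
    abort("config must be a list or a path to a YAML file",
      class = "dhalokin_config_error"
    )
  }
  config
}

config_hash <- function(config) {
  # stable content hash without extra dependencies: sum over the serialized
  # config bytes (enough to detect accidental config drift in reports)
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}

#' Generate synthetic kinetic datasets from a config
#'
#' Config blocks: `mechanism` (+ rate constants), `observable` (or `species`
#' for the identity observable), `design` (mode, concentrations, grid,
#' noise), `seed`, `outdir`. Writes the dataset CSV(s) and a JSON manifest
#' recording the generating parameters.
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, a list with the dataset and the file paths written.
#' @export
run_simulate <- function(config) {
  config <- resolve_config(config)
  if (is.null(config$mechanism)) {
    abort("config: missing mechanism block", class = "dhalokin_config_error")
  }
  if (is.null(config$design)) {
    abort("config: missing design block", class = "dhalokin_config_error")
  }
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  mech <- config_mechanism(config$mechanism)
  des_args <- config$design
  des_args$seed <- seed
  design <- do.call(experiment_design, des_args)

  if (design$mode == "stopped_flow") {
    rates <- config_rates(config$mechanism)
    coeffs <- config_observable(config$observable)
    if (is.null(coeffs)) {
      abort("config: stopped_flow simulation requires an observable block",
        class = "dhalokin_config_error"
      )
    }
    ds <- generate_stopped_flow_dataset(mech, rates, coeffs, design)
    path <- file.path(outdir, "traces.csv")
    write_trace_csv(ds$traces, path, meta = list(seed = seed))
  } else {
    ss <- config$steady_state
    if (is.null(ss$kcat) || is.null(ss$Km)) {
      abort("config: steady_state simulation requires kcat and Km",
        class = "dhalokin_config_error"
      )
    }
    ds <- generate_initial_rate_dataset(
      as.numeric(ss$kcat), as.numeric(ss$Km),
      design$enzyme_conc, design
    )
    path <- file.path(outdir, "initial_rates.csv")
    write_initial_rate_csv(ds$initial_rates, path, meta = list(seed = seed))
  }

  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    mode = design$mode,
    files = basename(path),
    truth = ds$truth[setdiff(names(ds$truth), c("rates", "coeffs", "mechanism", "design"))]
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, files = c(path, manifest_path)))
}

#' Fit a kinetic dataset from a config
#'
#' Reads the dataset file(s) named in the config, runs [global_fit()] (for
#' traces) and/or [fit_michaelis_menten()] (for initial rates), optionally
#' profiles requested parameters with [confidence_contours()], and writes a
#' JSON report containing estimates, standard errors, chi2, contour limits,
#' derived constants with propagated errors and the rate-limiting step.
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the report list (also written to
#'   `<outdir>/fit_report.json`).
#' @export
run_fit <- function(config) {
  config <- resolve_config(config)
  if (is.null(config$mechanism)) {
    abort("config: missing mechanism block", class = "dhalokin_config_error")
  }
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  mech <- config_mechanism(config$mechanism)
  rates <- config_rates(config$mechanism)
  coeffs <- config_observable(config$observable)

  report <- list(seed = seed, config_hash = config_hash(config))

  if (!is.null(config$traces_file)) {
    traces <- read_trace_csv(config$traces_file)
    ds <- new_kinetic_dataset(traces, empty_initial_rates(), truth = list())
    free <- config$fit$free %||% c("k2", "k3")
    fit <- global_fit(ds, mech, rates, coeffs,
      free = free,
      n_starts = config$fit$n_starts %||% 5,
      restart_seed = seed,
      conc_adjust = isTRUE(config$fit$conc_adjust)
    )
    report$global_fit <- list(
      estimates = as.list(fit$estimates),
      standard_errors = as.list(fit$standard_errors),
      chi2_min = fit$chi2_min,
      n_points = fit$n_points,
      n_params = fit$n_params,
      converged = fit$converged
    )
    for (pp in config$fit$contours %||% character()) {
      if (!pp %in% free) {
        warn(paste0("contour requested for a fixed parameter, skipped: ", pp))
        next
      }
      cr <- confidence_contours(fit, pp)
      report$contours[[pp]] <- list(
        lower = cr$lower, upper = cr$upper,
        lower_bounded = cr$lower_bounded, upper_bounded = cr$upper_bounded,
        threshold = cr$threshold
      )
    }
    rl <- rate_limiting_step(fit$rates, mech)
    if (length(rl)) report$rate_limiting_step <- rl
    if (!is.na(fit$rates$k1) && !is.na(fit$rates$k_minus1) &&
      all(c("k1", "k_minus1") %in% free)) {
      pr <- propagate_ratio_error(
        fit$estimates[["k_minus1"]], fit$standard_errors[["k_minus1"]],
        fit$estimates[["k1"]], fit$standard_errors[["k1"]]
      )
      report$Ks <- list(value = pr$ratio, se = pr$se)
    }
  }

  if (!is.null(config$initial_rates_file)) {
    ir <- read_initial_rate_csv(config$initial_rates_file)
    mm <- fit_michaelis_menten(ir)
    spec <- specificity(mm$kcat, mm$Km, mm$se_kcat, mm$se_Km)
    report$mm_fit <- list(
      kcat = mm$kcat, kcat_se = mm$se_kcat,
      Km = mm$Km, Km_se = mm$se_Km,
      kcat_over_Km = spec$kcat_over_Km, kcat_over_Km_se = spec$se,
      chi2_min = mm$chi2_min, flag = mm$flag
    )
  }

  if (is.null(report$global_fit) && is.null(report$mm_fit)) {
    abort("config: neither traces_file nor initial_rates_file given",
      class = "dhalokin_config_error"
    )
  }

  path <- file.path(outdir, "fit_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  validate_report(report, "fit")
  invisible(report)
}

#' Build and validate a Markov state model from a config
#'
#' Pipeline: read trajectory/feature CSVs, (optionally) binary-contact
#' featurize and run [tica()], cluster into microstates, estimate the
#' transition model, compute implied timescales and the Chapman-Kolmogorov
#' discrepancies; optionally decompose pathway flux and classify NAC
#' geometries. Writes a JSON summary.
#'
#' Config keys: `dtrajs_file` (CSV with columns `traj`, `frame`, `state`) or
#' `features_file` (CSV `traj`, `frame`, `feat_*`), `msm` block
#' (`contact_cutoff`, `tica_lag`, `tica_dims`, `n_clusters`, `msm_lag`,
#' `reversible`, `its_lags`, `ck_factors`), optional `flux` block (`source`,
#' `sink`, `channels`), optional `nac_file` (CSV `distance_A`, `angle_deg`).
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the report list (written to
#'   `<outdir>/msm_report.json`).
#' @export
run_msm <- function(config) {
  config <- resolve_config(config)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  msm_cfg <- config$msm %||% list()
  report <- list(seed = seed, config_hash = config_hash(config))

  dtrajs <- NULL
  if (!is.null(config$features_file)) {
    feats <- read_csv_with_meta(config$features_file)
    if (!nrow(feats)) {
      abort("features file is empty", class = "dhalokin_config_error")
    }
    featcols <- grep("^feat_", names(feats), value = TRUE)
    blocks <- purrr::map(
      split(feats[featcols], feats$traj %||% 1L),
      as.matrix
    )
    if (!is.null(msm_cfg$contact_cutoff)) {
      blocks <- purrr::map(blocks, binary_contact_featurize,
        cutoff = msm_cfg$contact_cutoff
      )
    }
    tica_lag <- msm_cfg$tica_lag %||% 5L
    if (any(vapply(blocks, nrow, 1L) <= tica_lag)) {
      abort("trajectory shorter than the TICA lag", class = "dhalokin_config_error")
    }
    tc <- tica(blocks,
      lag = tica_lag,
      n_components = msm_cfg$tica_dims %||% min(5L, length(featcols))
    )
    cl <- cluster_microstates(tc$projections,
      n_clusters = msm_cfg$n_clusters %||% 200L, seed = seed
    )
    lens <- vapply(blocks, nrow, 1L)
    idx <- rep(seq_along(blocks), lens)
    dtrajs <- split(cl$assignments - 1L, idx)
    report$tica_eigenvalues <- tc$eigenvalues
  } else if (!is.null(config$dtrajs_file)) {
    dd <- read_csv_with_meta(config$dtrajs_file)
    if (!nrow(dd)) {
      abort("discrete-trajectory file is empty", class = "dhalokin_config_error")
    }
    dtrajs <- purrr::map(split(dd$state, dd$traj %||% 1L), as.integer)
  } else {
    abort("config: need features_file or dtrajs_file",
      class = "dhalokin_config_error"
    )
  }

  lag <- msm_cfg$msm_lag %||% 1L
  model <- estimate_transition_model(dtrajs,
    lag = lag,
    reversible = isTRUE(msm_cfg$reversible)
  )
  report$n_states <- nrow(model$transition_matrix)
  report$lag <- model$lag
  report$equilibrium_distribution <- model$equilibrium_distribution

  its_lags <- msm_cfg$its_lags %||% unique(pmax(1L, c(lag, 2L * lag, 5L * lag)))
  its <- implied_timescales(dtrajs, its_lags, reversible = isTRUE(msm_cfg$reversible))
  report$implied_timescales <- its[its$index == 2, c("lag", "timescale")]

  ck <- ck_test(dtrajs, model, factors = msm_cfg$ck_factors %||% c(2L, 5L))
  report$ck_max_discrepancy <- purrr::map_dbl(ck, "max_discrepancy")

  if (!is.null(config$flux)) {
    fl <- pathway_fractions(
      model,
      source_states = as.integer(config$flux$source),
      sink_states = as.integer(config$flux$sink),
      channel_map = purrr::map(config$flux$channels, as.integer)
    )
    report$pathway_fractions <- setNames(as.list(fl$fraction), fl$channel)
  }

  if (!is.null(config$nac_file)) {
    geo <- read_csv_with_meta(config$nac_file)
    cls <- classify_nac(geo)
    report$nac_fraction <- nac_fraction(cls)
  }

  path <- file.path(outdir, "msm_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  validate_report(report, "msm")
  invisible(report)
}

# Minimal structural validation of pipeline reports against the JSON schema
# files shipped under inst/schema (required keys and types).
validate_report <- function(report, kind = c("fit", "msm")) {
  kind <- match.arg(kind)
  schema_path <- system.file("schema", paste0(kind, "_report.schema.json"),
    package = "dhalokin"
  )
  required <- if (nzchar(schema_path) && file.exists(schema_path)) {
    jsonlite::read_json(schema_path)$required
  } else {
    list("seed", "config_hash")
  }
  miss <- setdiff(unlist(required), names(report))
  if (length(miss)) {
    abort(paste0("report missing required field(s): ", paste(miss, collapse = ", ")),
      class = "dhalokin_validation_error"
    )
  }
  invisible(TRUE)
}
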