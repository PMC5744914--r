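# Config-driven experiment runner and deterministic test fixtures.

.protocols <- c("rate_mtf", "phase_tuning", "ild_tuning", "impedance",
                "iv", "step", "psp", "table1")

#' Experiment configuration
#'
#' Validated configuration for [run_experiment()]. Unknown fields are
#' rejected. The defaults (`profile = "paper2017"`) reproduce the published
#' calibration protocols: 40 s per stimulus point, dt = 2 microseconds,
#' modulation frequencies 50-1200 Hz in 50 Hz steps, 16 phase points per
#' cycle, contralateral levels -10 to +50 dB in 5 dB steps at an ipsilateral
#' level of +35 dB.
#'
#' @param model one of [lso_model_ids()].
#' @param protocol one of `rate_mtf`, `phase_tuning`, `ild_tuning`,
#'   `impedance`, `iv`, `step`, `psp`, `table1`.
#' @param seed master seed.
#' @param dt integration step, ms.
#' @param duration stimulus duration per point, s.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param overrides named list of parameter overrides passed to the model's
#'   parameter constructor.
#' @param profile named defaults profile; only `"paper2017"` is defined.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(model, protocol, seed = 1L, dt = 0.002,
                              duration = 40, out_dir = NULL,
                              overrides = list(), profile = "paper2017") {
  if (!model %in% lso_model_ids()) abort(paste0("unknown model: ", model))
  if (!protocol %in% .protocols) abort(paste0("unknown protocol: ", protocol))
  if (!identical(profile, "paper2017")) abort("only the 'paper2017' profile is defined")
  if (!is.list(overrides)) abort("`overrides` must be a named list")
  structure(list(model = model, protocol = protocol, seed = as.integer(seed),
                 dt = dt, duration = duration, out_dir = out_dir,
                 overrides = overrides, profile = profile),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Unknown keys are rejected by [experiment_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  do.call(experiment_config, raw)
}

config_model <- function(config) {
  params <- if (length(config$overrides) == 0) NULL else {
    ctor <- switch(config$model,
      coincidence = coincidence_params,
      stein_exp = function(...) stein_params("exponential", ...),
      stein_alpha = function(...) stein_params("alpha", ...),
      if_passive = passive_if_params,
      if_active = active_if_params,
      wc_original = function(...) wang_colburn_params("original", ...),
      wc_adjusted = function(...) wang_colburn_params("adjusted", ...)
    )
    do.call(ctor, config$overrides)
  }
  lso_model(config$model, params = params)
}

#' Run a configured experiment
#'
#' Executes the configured protocol and, if `out_dir` is set, writes the
#' result as CSV plus a JSON sidecar (model, protocol, seed, dt, duration,
#' parameter set) and a plain-text log. Outputs are deterministic for a
#' fixed configuration.
#'
#' @param config an [experiment_config()] or a path readable by
#'   [read_experiment_config()].
#' @return the protocol result (an `lso_tuning`, `lso_iv`, tibble, or for
#'   `table1` a list with curves and score), invisibly carrying the written
#'   file paths in attribute `"files"`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  model <- config_model(config)
  dt <- config$dt
  res <- switch(config$protocol,
    rate_mtf = rate_mtf(model, duration = config$duration, seed = config$seed, dt = dt),
    phase_tuning = phase_tuning(model, duration = config$duration, seed = config$seed, dt = dt),
    ild_tuning = ild_tuning(model, duration = config$duration, seed = config$seed, dt = dt),
    impedance = impedance_profile(model, dt = dt),
    iv = iv_curve(model, dt = dt),
    step = classify_step_response(model, dt = dt),
    psp = dplyr::bind_rows(
      ex = psp_metrics(unitary_psp("ex", model$synapse, dt = dt)),
      inh = psp_metrics(unitary_psp("inh", model$synapse, dt = dt)),
      .id = "kind"),
    table1 = calibration_battery(model, duration = config$duration,
                                 seed = config$seed, dt = dt)
  )
  if (!is.null(config$out_dir)) {
    attr(res, "files") <- write_experiment_outputs(res, config)
  }
  invisible(res)
}

write_experiment_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(config$out_dir, paste0(config$model, "_", config$protocol))
  files <- character(0)
  write_csv_plain <- function(df, path) {
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    path
  }
  if (config$protocol == "table1") {
    for (nm in names(res$curves)) {
      files <- c(files, write_csv_plain(res$curves[[nm]],
                                        paste0(stem, "_", nm, ".csv")))
    }
    files <- c(files, write_csv_plain(res$score, paste0(stem, "_score.csv")))
  } else if (inherits(res, "lso_iv")) {
    files <- c(files, write_csv_plain(res$iv, paste0(stem, ".csv")))
  } else {
    files <- c(files, write_csv_plain(res, paste0(stem, ".csv")))
  }
  meta <- list(model = config$model, protocol = config$protocol,
               seed = config$seed, dt = config$dt,
               duration = config$duration, profile = config$profile,
               params = unclass(config_model(config)$params),
               params_hash = params_hash(config_model(config)$params),
               package_version = as.character(utils::packageVersion("olivesim")))
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  log_path <- paste0(stem, ".log")
  writeLines(c(
    paste0("olivesim ", meta$package_version),
    paste0("model=", config$model, " protocol=", config$protocol),
    paste0("seed=", config$seed, " dt_ms=", format(config$dt),
           if (config$dt != 0.002) "  [non-default dt]" else ""),
    paste0("duration_s=", config$duration),
    paste0("params_hash=", meta$params_hash)
  ), log_path)
  c(files, json_path, log_path)
}

# small deterministic hash of a parameter list (djb2 over its deparse)
params_hash <- function(params) {
  s <- paste(deparse(unclass(params)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

# --- deterministic fixtures ---------------------------------------------------

fixture_registry <- function() {
  ms <- function(x) x / 1000
  list(
    empty = list(ex = numeric(0), inh = numeric(0)),
    single_ex = list(ex = ms(1), inh = numeric(0)),
    single_inh = list(ex = numeric(0), inh = ms(1)),
    five_coincident = list(ex = rep(ms(1), 5), inh = numeric(0)),
    six_coincident = list(ex = rep(ms(1), 6), inh = numeric(0)),
    eight_coincident = list(ex = rep(ms(1), 8), inh = numeric(0)),
    # two suprathreshold clusters 1.0 ms apart (inside T_ref = 1.6 ms)
    cluster_pair_1ms = list(ex = c(rep(ms(1), 8), rep(ms(2), 8)),
                            inh = numeric(0)),
    ex_plus_inh_simultaneous = list(ex = ms(1), inh = ms(1)),
    # eight coincident excitatory spikes preceded by one inhibitory spike
    eight_with_leading_inh = list(ex = rep(ms(1), 8), inh = ms(0.5))
  )
}

#' Hand-placed deterministic spike fixtures
#'
#' A small registry of exactly specified input patterns used by the unit
#' tests of the threshold models (e.g. `"eight_coincident"`: eight excitatory
#' spikes at 1.0 ms; `"cluster_pair_1ms"`: two suprathreshold clusters 1 ms
#' apart; `"ex_plus_inh_simultaneous"`).
#'
#' @param name fixture name; see `names(olivesim:::fixture_registry())`.
#' @param duration nominal duration, s.
#' @return an `lso_spikes` tibble.
#' @export
make_fixture <- function(name, duration = 0.01) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    abort(paste0("unknown fixture: ", name, " (available: ",
                 paste(names(reg), collapse = ", "), ")"))
  }
  fx <- reg[[name]]
  df <- tibble(
    fiber = c(seq_along(fx$ex), 20L + seq_along(fx$inh)),
    pop = c(rep("ex", length(fx$ex)), rep("inh", length(fx$inh))),
    time = c(fx$ex, fx$inh)
  )
  new_lso_spikes(df, new_stimulus(list(mode = "fixture", name = name,
                                       duration = duration)),
                 input_ensemble_config(M_ex = 20L, M_inh = 8L), seed = 0L)
}
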