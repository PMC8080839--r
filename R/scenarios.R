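#' Build one scenario configuration
#'
#' A scenario is the basic study design (50-step bifurcation sweep, 10,000
#' samples per step at interval 0.1, additive system noise 0.02, no
#' measurement noise, all variables observed) plus at most one named
#' deviation. The seven canonical scenarios are produced by
#' [scenario_presets()].
#'
#' @param name One of `basic`, `data_length`, `data_resolution`,
#'   `measurement_noise`, `multiplicative_noise`, `subset_variables`,
#'   `reactive`.
#' @param model_setting `"4d"`, `"20d_full"` or `"20d_partial"`. The reactive
#'   scenario is only available for the 4-species model.
#' @param length Samples per sweep step.
#' @param sampling_interval Time units between samples.
#' @param noise A [noise_spec()].
#' @param subset_fraction Fraction of variables observed (`NULL` unless the
#'   subset scenario).
#' @param n_sweep_steps Number of sweep steps (default 50).
#' @param seed Master seed.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(name, model_setting = "4d", length = 10000,
                            sampling_interval = 0.1, noise = noise_spec(),
                            subset_fraction = NULL, n_sweep_steps = 50L,
                            seed = 1L) {
  valid <- c("basic", "data_length", "data_resolution", "measurement_noise",
             "multiplicative_noise", "subset_variables", "reactive")
  if (!name %in% valid)
    stop_parameter("unknown scenario '", name, "'")
  if (!model_setting %in% c("4d", "20d_full", "20d_partial"))
    stop_parameter("unknown model_setting '", model_setting, "'")
  if (name == "reactive" && model_setting != "4d")
    stop_parameter("the reactive scenario is only defined for the 4d model ",
                   "(the 20-species model cannot be tuned reactive)")
  structure(list(name = name, model_setting = model_setting,
                 length = length, sampling_interval = sampling_interval,
                 noise = noise, subset_fraction = subset_fraction,
                 n_sweep_steps = as.integer(n_sweep_steps),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s' (%s): length %g @ interval %g, %s noise %g, ",
              x$name, x$model_setting, x$length, x$sampling_interval,
              x$noise$mode, x$noise$sigma[1]))
  cat(sprintf("measurement sd %g%s\n", x$noise$measurement_sd,
              if (!is.null(x$subset_fraction))
                sprintf(", subset fraction %g", x$subset_fraction) else ""))
  invisible(x)
}

#' The canonical scenario catalogue
#'
#' Six data/system scenarios for each of the three model settings, plus the
#' reactive scenario for the 4-species model only: 19 configurations. Each
#' preset deviates from `basic` in exactly one respect: `data_length` shortens
#' the series to 1,000 samples; `data_resolution` keeps 10,000 samples but
#' samples every 100 time units (longer simulations, not thinned ones);
#' `measurement_noise` adds N(0, 0.08^2) to every datapoint afterwards;
#' `multiplicative_noise` scales the Wiener increments by the current
#' abundance; `subset_variables` analyses every half-sized variable subset;
#' `reactive` switches to the reactive model tuning.
#'
#' @param seed Master seed stored in each preset.
#' @return List of [scenario_config()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  settings <- c("4d", "20d_full", "20d_partial")
  shared <- c("basic", "data_length", "data_resolution", "measurement_noise",
              "multiplicative_noise", "subset_variables")
  out <- list()
  for (ms in settings) {
    for (nm in shared) {
      out[[paste(ms, nm, sep = ".")]] <- preset_one(nm, ms, seed)
    }
  }
  out[["4d.reactive"]] <- preset_one("reactive", "4d", seed)
  out
}

preset_one <- function(name, model_setting, seed) {
  cfg <- scenario_config("basic", model_setting, seed = seed)
  cfg$name <- name
  switch(name,
         basic = NULL,
         data_length = { cfg$length <- 1000 },
         data_resolution = { cfg$sampling_interval <- 100 },
         measurement_noise = { cfg$noise$measurement_sd <- 0.08 },
         multiplicative_noise = { cfg$noise$mode <- "multiplicative" },
         subset_variables = { cfg$subset_fraction <- 0.5 },
         reactive = NULL)
  if (name == "reactive" && model_setting != "4d")
    stop_parameter("reactive preset is 4d-only")
  cfg
}

#' Run one scenario: sweep, simulate, apply the scenario's transforms
#'
#' Builds (or accepts) the bifurcation sweep for the configured model
#' setting, simulates the stationary series at every sweep step and applies
#' the scenario's degradations. The subset scenario is not expanded here:
#' subsets are column slices of the returned series, enumerated lazily by
#' [evaluate_subsets()] so all subsets share the same latent paths.
#'
#' @param config A [scenario_config()].
#' @param model For the 20d settings, a [random_parameter_search()] result
#'   (required); ignored for `4d`, where the default tunings are used.
#' @param scale Factor in (0, 1] multiplying the series length, for
#'   desk-scale runs.
#' @param sweep Optionally a precomputed [sweep_stability()] result, reused
#'   across scenarios to avoid repeating the continuation.
#' @return A `sweep_series` object (see [generate_sweep_series()]).
#' @export
run_scenario <- function(config, model = NULL, scale = 1, sweep = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (scale <= 0 || scale > 1) stop_parameter("scale must be in (0, 1]")
  if (is.null(sweep)) sweep <- scenario_sweep(config, model)
  len <- max(50L, as.integer(round(config$length * scale)))
  out <- generate_sweep_series(sweep, noise = config$noise, length = len,
                               sampling_interval = config$sampling_interval,
                               seed = config$seed)
  if (config$noise$measurement_sd > 0) {
    out$series <- lapply(seq_along(out$series), function(s)
      add_measurement_noise(out$series[[s]], config$noise$measurement_sd,
                            seed = derive_seed(config$seed, 1000L, s)))
  }
  out$config <- config
  out
}

scenario_sweep <- function(config, model = NULL) {
  if (config$model_setting == "4d") {
    reactive <- identical(config$name, "reactive")
    rng <- default_sweep_4d(reactive)
    params <- params_4d(reactive, r_A = rng$r_A_start,
                        sigma = config$noise$sigma)
    sweep_stability(params, rng$r_A_start, rng$r_A_end,
                    n_steps = config$n_sweep_steps)
  } else {
    if (is.null(model))
      stop_parameter("model_setting '", config$model_setting, "' needs a ",
                     "random_parameter_search() result in `model`")
    stopifnot(inherits(model, "pp_search_result"))
    sweep_stability(model$params, model$r_A_start, model$r_A_end,
                    n_steps = config$n_sweep_steps)
  }
}

#' One-axis sensitivity grids
#'
#' Produces one configuration per grid value, everything else fixed at the
#' base configuration: series length, sampling interval (resolution), or
#' measurement-noise standard deviation (the accuracy axis, typically swept
#' over 0 to 0.3).
#'
#' @param axis `"length"`, `"resolution"` or `"measurement_sd"`.
#' @param values Numeric grid values.
#' @param base Base [scenario_config()].
#' @return List of configurations (possibly empty).
#' @export
sensitivity_grid <- function(axis = c("length", "resolution",
                                      "measurement_sd"),
                             values, base = scenario_config("basic")) {
  axis <- match.arg(axis)
  lapply(values, function(v) {
    if (v <= 0 && axis != "measurement_sd")
      stop_parameter("grid values must be positive")
    if (v < 0) stop_parameter("measurement_sd must be >= 0")
    cfg <- base
    switch(axis,
           length = { cfg$length <- v },
           resolution = { cfg$sampling_interval <- v },
           measurement_sd = { cfg$noise$measurement_sd <- v })
    cfg
  })
}
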