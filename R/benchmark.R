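#' Run the indicator benchmark end to end
#'
#' One call reproduces any column of the benchmark at configurable scale:
#' build the sweep once per (model setting, tuning), simulate every requested
#' scenario with replicate master seeds, score the thirteen indicators, and
#' assemble the indicator x scenario performance table. Subset scenarios
#' contribute worst-case / best-case quantile rows instead of a point row.
#'
#' @param scenarios Character vector of scenario names (see
#'   [scenario_config()]).
#' @param model_setting `"4d"`, `"20d_full"` or `"20d_partial"`.
#' @param model 20d search result (required for the 20d settings).
#' @param replicates Replicate sweeps per scenario (distinct master seeds).
#' @param scale Series-length scale factor in (0, 1].
#' @param seed Master seed.
#' @param length,n_sweep_steps Base design values.
#' @param indicators Indicator names to score.
#' @param max_subsets Subset enumeration cap (see [evaluate_subsets()]).
#' @param out_dir Optional directory: writes `performance.csv`,
#'   `performance.json` and `manifest.json`.
#' @return List of class `ews_benchmark`: `table` (a `performance_table`),
#'   `entries` (per-replicate rows), `manifest`.
#' @export
run_benchmark <- function(scenarios = c("basic", "data_length",
                                        "data_resolution",
                                        "measurement_noise",
                                        "multiplicative_noise",
                                        "subset_variables"),
                          model_setting = "4d", model = NULL,
                          replicates = 10L, scale = 1, seed = 1L,
                          length = 10000, n_sweep_steps = 50L,
                          indicators = indicator_names(),
                          max_subsets = 5000L, out_dir = NULL) {
  t0 <- Sys.time()
  entries <- list()
  sweeps <- list()   # one continuation per tuning, shared across scenarios
  for (sc in scenarios) {
    cfg0 <- preset_one(sc, model_setting, seed)
    if (sc != "data_length") cfg0$length <- length
    cfg0$n_sweep_steps <- as.integer(n_sweep_steps)
    tuning <- if (identical(sc, "reactive")) "reactive" else "default"
    if (is.null(sweeps[[tuning]]))
      sweeps[[tuning]] <- scenario_sweep(cfg0, model)
    for (r in seq_len(replicates)) {
      cfg <- cfg0
      cfg$seed <- derive_seed(seed, match(sc, scenarios), r)
      ss <- run_scenario(cfg, model = model, scale = scale,
                         sweep = sweeps[[tuning]])
      if (identical(sc, "subset_variables")) {
        ev <- evaluate_subsets(ss, fraction = cfg$subset_fraction,
                               indicators = indicators,
                               max_subsets = max_subsets,
                               seed = derive_seed(seed, 999L, r))
        rows <- ev$summary
        rows$scenario <- sc
        rows$model_setting <- model_setting
        rows$replicate <- r
        rows$n_subsets <- NULL
        entries[[base::length(entries) + 1L]] <- rows
      } else {
        entries[[base::length(entries) + 1L]] <-
          sweep_performance(ss, indicators, replicate = r)
      }
    }
  }
  cols <- c("model_setting", "scenario", "indicator", "quantile_tag",
            "replicate", "raw_tau", "tau")
  entries <- do.call(rbind, lapply(entries, function(e) {
    if (is.null(e$quantile_tag)) e$quantile_tag <- "point"
    e[cols]
  }))
  table <- build_performance_table(entries)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ewsbench")),
    master_seed = seed, scenarios = scenarios,
    model_setting = model_setting, replicates = replicates, scale = scale,
    length = length, n_sweep_steps = n_sweep_steps,
    indicators = indicators,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_performance_table(table,
                            csv = file.path(out_dir, "performance.csv"),
                            json = file.path(out_dir, "performance.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$out_dir <- out_dir
  }
  structure(list(table = table, entries = entries, manifest = manifest),
            class = "ews_benchmark")
}

#' @export
print.ews_benchmark <- function(x, ...) {
  cat(sprintf("ews_benchmark: %s, %d scenario(s), %d replicate(s), scale %g\n",
              x$manifest$model_setting, length(x$manifest$scenarios),
              x$manifest$replicates, x$manifest$scale))
  print(x$table)
  invisible(x)
}

#' Validate a scenario configuration without running it
#'
#' @param config A [scenario_config()] or a path to a YAML file with its
#'   fields.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste0("config file not found: ", config))
    f <- yaml::read_yaml(config)
    problems <- character()
    tryCatch({
      config <- scenario_config(
        name = f$name %||% "basic",
        model_setting = f$model_setting %||% "4d",
        length = f$length %||% 10000,
        sampling_interval = f$sampling_interval %||% 0.1,
        noise = noise_spec(f$noise_mode %||% "additive",
                           f$sigma %||% 0.02, f$measurement_sd %||% 0),
        subset_fraction = f$subset_fraction,
        n_sweep_steps = f$n_sweep_steps %||% 50L,
        seed = f$seed %||% 1L)
    }, error = function(e) {
      problems <<- c(problems, conditionMessage(e))
    })
    if (length(problems)) return(problems)
  }
  problems <- character()
  if (!inherits(config, "scenario_config"))
    return("not a scenario_config object")
  if (config$length < 2)
    problems <- c(problems, "length must be at least 2 samples")
  if (config$sampling_interval <= 0)
    problems <- c(problems, "sampling_interval must be positive")
  if (config$name == "reactive" && config$model_setting != "4d")
    problems <- c(problems, "reactive scenario requires the 4d model")
  if (!is.null(config$subset_fraction) &&
      (config$subset_fraction <= 0 || config$subset_fraction >= 1))
    problems <- c(problems, "subset_fraction must be in (0, 1)")
  if (config$n_sweep_steps < 3)
    problems <- c(problems, "need at least 3 sweep steps for a trend")
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(list(
    name = config$name, model_setting = config$model_setting,
    length = config$length, sampling_interval = config$sampling_interval,
    noise_mode = config$noise$mode, sigma = config$noise$sigma,
    measurement_sd = config$noise$measurement_sd,
    subset_fraction = config$subset_fraction,
    n_sweep_steps = config$n_sweep_steps, seed = config$seed), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  f <- yaml::read_yaml(path)
  scenario_config(
    name = f$name, model_setting = f$model_setting %||% "4d",
    length = f$length %||% 10000,
    sampling_interval = f$sampling_interval %||% 0.1,
    noise = noise_spec(f$noise_mode %||% "additive", f$sigma %||% 0.02,
                       f$measurement_sd %||% 0),
    subset_fraction = f$subset_fraction,
    n_sweep_steps = f$n_sweep_steps %||% 50L, seed = f$seed %||% 1L)
}

#' @export
summary.ews_benchmark <- function(object, ...) object$table
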