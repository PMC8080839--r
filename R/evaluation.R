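#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation over all pairs; the trend statistic used
#' to score indicators along a sweep.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Value in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop_dimension("x and y must have equal length")
  if (length(x) < 2) stop_parameter("need at least 2 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_degenerate("Kendall tau is undefined when one input is all tied")
  stats::cor(x, y, method = "kendall")
}

#' Score one indicator trajectory along a sweep
#'
#' Applies the indicator's declared orientation (values of
#' decreases-toward-transition indicators are negated so every indicator is
#' scored as a rising signal), computes the Kendall tau against the step
#' index (the distance to the bifurcation, decreasing), and clips negative
#' correlations at zero.
#'
#' @param values Indicator values along the sweep steps.
#' @param orientation `"increases_toward_transition"` or
#'   `"decreases_toward_transition"`.
#' @param indicator,scenario,model_setting,replicate Label fields copied into
#'   the result row.
#' @param quantile_tag `"point"`, or the subset tags set by
#'   [subset_performance()].
#' @return One-row data frame: `indicator`, `scenario`, `model_setting`,
#'   `quantile_tag`, `replicate`, `raw_tau`, `tau`, `n_steps`, `flagged`.
#' @export
indicator_performance <- function(values, orientation =
                                    "increases_toward_transition",
                                  indicator = NA_character_,
                                  scenario = NA_character_,
                                  model_setting = NA_character_,
                                  replicate = 1L,
                                  quantile_tag = "point") {
  ok <- is.finite(values)
  if (sum(ok) < 3)
    stop_evaluation("need at least 3 finite sweep values")
  if (mean(!ok) > 0.1)
    stop_evaluation("more than 10% of sweep steps failed")
  v <- values[ok]
  steps <- seq_along(values)[ok]
  oriented <- if (identical(orientation, "decreases_toward_transition"))
    -v else v
  flagged <- FALSE
  raw_tau <- if (length(unique(oriented)) < 2) {
    flagged <- TRUE  # constant indicator: no trend
    0
  } else {
    kendall_tau(oriented, steps)
  }
  data.frame(indicator = indicator, scenario = scenario,
             model_setting = model_setting, quantile_tag = quantile_tag,
             replicate = replicate, raw_tau = raw_tau,
             tau = max(raw_tau, 0), n_steps = length(v), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Indicator trajectories along a simulated sweep
#'
#' @param sweep_series A [generate_sweep_series()] / [run_scenario()] result.
#' @param indicators Indicator names (default all 13).
#' @param columns Optional column subset applied to every step before
#'   computing the indicators.
#' @return Matrix with one row per sweep step and one column per indicator
#'   (excluded steps are `NA`).
#' @export
sweep_indicators <- function(sweep_series, indicators = indicator_names(),
                             columns = NULL) {
  stopifnot(inherits(sweep_series, "sweep_series"))
  n <- length(sweep_series$series)
  out <- matrix(NA_real_, n, length(indicators),
                dimnames = list(NULL, indicators))
  for (s in seq_len(n)) {
    if (s %in% sweep_series$excluded) next
    ts <- sweep_series$series[[s]]
    if (!is.null(columns)) ts <- select_subset(ts, columns)
    for (nm in indicators)
      out[s, nm] <- compute_indicator(nm, ts)$value
  }
  out
}

#' Score all indicators on a simulated sweep
#'
#' @inheritParams sweep_indicators
#' @param replicate Replicate label stored in the rows.
#' @return Data frame of [indicator_performance()] rows.
#' @export
sweep_performance <- function(sweep_series, indicators = indicator_names(),
                              columns = NULL, replicate = 1L) {
  vals <- sweep_indicators(sweep_series, indicators, columns)
  cfg <- sweep_series$config
  rows <- lapply(indicators, function(nm)
    indicator_performance(vals[, nm],
                          orientation = .indicator_orientation[[nm]],
                          indicator = nm,
                          scenario = if (is.null(cfg)) NA_character_ else
                            cfg$name,
                          model_setting = if (is.null(cfg)) NA_character_ else
                            cfg$model_setting,
                          replicate = replicate))
  do.call(rbind, rows)
}

#' Worst-case / best-case performance over variable subsets
#'
#' Summarizes subset raw taus as their empirical 5% ("worst case") and 95%
#' ("best case") quantiles (linear interpolation), clipped at zero.
#'
#' @param raw_taus Numeric vector of raw (unclipped) Kendall taus, one per
#'   subset.
#' @return Data frame with rows tagged `worst_case_5pct` / `best_case_95pct`.
#' @export
subset_performance <- function(raw_taus) {
  raw_taus <- raw_taus[is.finite(raw_taus)]
  if (length(raw_taus) < 2)
    stop_evaluation("need at least 2 subset taus")
  q <- stats::quantile(raw_taus, c(0.05, 0.95), type = 7, names = FALSE)
  data.frame(quantile_tag = c("worst_case_5pct", "best_case_95pct"),
             raw_tau = q, tau = pmax(q, 0), n_subsets = length(raw_taus),
             stringsAsFactors = FALSE)
}

#' Enumerate (or sample) variable subsets and score every indicator on each
#'
#' Slices the already-simulated sweep column-wise so every subset shares the
#' same latent sample paths. Full enumeration is used when the number of
#' subsets is at most `max_subsets`; otherwise `max_subsets` subsets are
#' sampled uniformly without replacement (fixed seed), which keeps the
#' 20-species case (choose(20, 10) = 184,756 subsets) at desk scale.
#'
#' @param sweep_series A simulated sweep.
#' @param fraction Fraction of variables per subset (default 0.5).
#' @param indicators Indicator names.
#' @param max_subsets Enumeration cap (default 5000).
#' @param seed Seed for subset sampling beyond the cap.
#' @return List with `raw` (matrix subsets x indicators of raw taus),
#'   `subsets` (list of index vectors) and `summary` (per-indicator
#'   worst/best-case rows from [subset_performance()]).
#' @export
evaluate_subsets <- function(sweep_series, fraction = 0.5,
                             indicators = indicator_names(),
                             max_subsets = 5000L, seed = 1L) {
  stopifnot(inherits(sweep_series, "sweep_series"))
  N <- ncol(sweep_series$series[[1]]$values)
  m <- max(1L, round(N * fraction))
  n_all <- choose(N, m)
  subsets <- if (n_all <= max_subsets) {
    asplit(utils::combn(N, m), 2)
  } else {
    with_private_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- list()
      while (length(out) < max_subsets) {
        s <- sort(sample.int(N, m))
        key <- paste(s, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- s
        }
      }
      out
    })
  }
  raw <- matrix(NA_real_, length(subsets), length(indicators),
                dimnames = list(NULL, indicators))
  for (i in seq_along(subsets)) {
    perf <- sweep_performance(sweep_series, indicators,
                              columns = as.integer(subsets[[i]]))
    raw[i, ] <- perf$raw_tau[match(indicators, perf$indicator)]
  }
  summary <- do.call(rbind, lapply(indicators, function(nm) {
    sp <- subset_performance(raw[, nm])
    sp$indicator <- nm
    sp
  }))
  list(raw = raw, subsets = subsets, summary = summary)
}

#' Assemble the indicator x scenario performance table
#'
#' Aggregates replicate rows by their mean (dispersion retained as the
#' standard deviation) over the grid cells
#' (model_setting, scenario, indicator, quantile_tag). The same replicate
#' appearing twice in a cell is an assembly error.
#'
#' @param entries Data frame of [indicator_performance()] /
#'   [subset_performance()] rows bound together.
#' @return Long-format data frame of class `performance_table` with columns
#'   `model_setting`, `scenario`, `indicator`, `quantile_tag`, `tau`,
#'   `raw_tau`, `sd_tau`, `n_replicates`.
#' @export
build_performance_table <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0) {
    out <- data.frame(model_setting = character(), scenario = character(),
                      indicator = character(), quantile_tag = character(),
                      tau = numeric(), raw_tau = numeric(),
                      sd_tau = numeric(), n_replicates = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("performance_table", "data.frame")
    return(out)
  }
  if (is.null(entries$quantile_tag)) entries$quantile_tag <- "point"
  if (is.null(entries$replicate)) entries$replicate <- 1L
  key <- interaction(entries$model_setting, entries$scenario,
                     entries$indicator, entries$quantile_tag,
                     entries$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop_evaluation("duplicate performance cell (same replicate appears ",
                    "twice in a cell)")
  cell <- interaction(entries$model_setting, entries$scenario,
                      entries$indicator, entries$quantile_tag, drop = TRUE)
  agg <- function(f, v) as.vector(tapply(v, cell, f))
  # tapply orders cells by factor level; align the label columns the same way
  idx <- match(levels(cell), as.character(cell))
  out <- data.frame(model_setting = entries$model_setting[idx],
                    scenario = entries$scenario[idx],
                    indicator = entries$indicator[idx],
                    quantile_tag = entries$quantile_tag[idx],
                    tau = agg(mean, entries$tau),
                    raw_tau = agg(mean, entries$raw_tau),
                    sd_tau = agg(stats::sd, entries$tau),
                    n_replicates = agg(length, entries$tau),
                    stringsAsFactors = FALSE)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' @export
print.performance_table <- function(x, digits = 2, ...) {
  if (nrow(x) == 0) {
    cat("performance_table: empty\n")
    return(invisible(x))
  }
  for (ms in unique(x$model_setting)) {
    sub <- x[x$model_setting == ms, ]
    col <- paste(sub$scenario, ifelse(sub$quantile_tag == "point", "",
                                      sub$quantile_tag))
    wide <- tapply(sub$tau, list(sub$indicator, col), mean)
    cat(sprintf("model setting: %s\n", ms))
    print(round(wide, digits))
  }
  invisible(x)
}

#' @export
plot.performance_table <- function(x, ...) {
  if (nrow(x) == 0) stop_parameter("empty performance table")
  sub <- x[x$model_setting == x$model_setting[1], ]
  col <- paste(sub$scenario, ifelse(sub$quantile_tag == "point", "",
                                    sub$quantile_tag))
  wide <- tapply(sub$tau, list(sub$indicator, col), mean)
  graphics::par(mar = c(9, 11, 2, 1))
  graphics::image(seq_len(ncol(wide)), seq_len(nrow(wide)), t(wide),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(50, "YlGnBu", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(wide)), colnames(wide), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(wide)), rownames(wide), las = 2,
                 cex.axis = 0.8)
  invisible(x)
}

#' Export a performance table as tidy CSV / JSON
#'
#' @param x A `performance_table`.
#' @param csv,json Optional output paths.
#' @export
write_performance_table <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "performance_table"))
  if (!is.null(csv)) utils::write.csv(x, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(x, json, dataframe = "rows", digits = NA)
  invisible(x)
}

#' Null-sweep specificity check
#'
#' Generates sweeps in which the bifurcation parameter never moves (every
#' step uses the parameters of the sweep start), so any apparent indicator
#' trend is spurious. Returns the per-indicator distribution of raw taus
#' across replicates; for a specific indicator battery these distributions
#' are centred at zero.
#'
#' @param config A [scenario_config()] (its scenario transforms are applied
#'   as usual, but the sweep is flat).
#' @param model 20d search result when needed (see [run_scenario()]).
#' @param n_replicates Number of independent null sweeps.
#' @param indicators Indicator names.
#' @param scale Series-length scale factor.
#' @return Data frame with columns `indicator`, `replicate`, `raw_tau`.
#' @export
specificity_null <- function(config, model = NULL, n_replicates = 10,
                             indicators = indicator_names(), scale = 1) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_replicates == 0)
    return(data.frame(indicator = character(), replicate = integer(),
                      raw_tau = numeric(), stringsAsFactors = FALSE))
  sweep <- scenario_sweep(config, model)
  # freeze the bifurcation parameter at the sweep start
  flat <- sweep
  flat$steps <- rep(sweep$steps[1], length(sweep$steps))
  flat$summary$eigenvalue <- flat$summary$eigenvalue[1]
  flat$summary$reactivity <- flat$summary$reactivity[1]
  flat$r_A_end <- flat$r_A_start

  out <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 2000L, r)
    ss <- run_scenario(cfg, model = model, scale = scale, sweep = flat)
    perf <- sweep_performance(ss, indicators, replicate = r)
    data.frame(indicator = perf$indicator, replicate = r,
               raw_tau = perf$raw_tau, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
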