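#' Multivariate time-series container
#'
#' A thin wrapper around a numeric `T x N` matrix carrying the sampling
#' interval, variable labels and provenance metadata (seed, scenario, sweep
#' step). This is the unit of exchange between the simulator, the
#' degradation transforms and the indicator stage.
#'
#' @param values Numeric matrix, rows = samples, columns = variables.
#' @param sampling_interval Time between consecutive rows (> 0).
#' @param labels Optional variable names (default from column names or `V1..`).
#' @param meta Named list of provenance fields.
#' @return An object of class `mvts`.
#' @export
mvts <- function(values, sampling_interval, labels = NULL, meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop_parameter("a time series needs at least 2 rows")
  if (any(!is.finite(values))) stop_parameter("values must be finite")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop_parameter("sampling_interval must be positive")
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(values)))
  }
  if (length(labels) != ncol(values))
    stop_dimension("labels length must match the number of columns")
  colnames(values) <- labels
  structure(list(values = values, sampling_interval = sampling_interval,
                 labels = labels, meta = meta),
            class = "mvts")
}

#' @export
print.mvts <- function(x, ...) {
  cat(sprintf("mvts: %d samples x %d variables, interval %g\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.mvts <- function(x, ...) x$values

#' @export
plot.mvts <- function(x, ...) {
  tt <- (seq_len(nrow(x$values)) - 1) * x$sampling_interval
  graphics::matplot(tt, x$values, type = "l", lty = 1, xlab = "time",
                    ylab = "abundance", ...)
  invisible(x)
}

#' Write / read an mvts as delimited text
#'
#' Tab-separated table with a leading `time` column and the variable labels
#' as a header.
#'
#' @param x An `mvts` object.
#' @param path File path.
#' @export
write_mvts <- function(x, path) {
  stopifnot(inherits(x, "mvts"))
  tt <- (seq_len(nrow(x$values)) - 1) * x$sampling_interval
  utils::write.table(data.frame(time = tt, x$values, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mvts
#' @param meta Metadata attached to the object read back.
#' @export
read_mvts <- function(path, meta = list()) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"time" %in% names(d) || nrow(d) < 2)
    stop_parameter("expected a 'time' column and at least 2 rows")
  dt <- diff(d$time)
  if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt)))
    stop_parameter("time column must be evenly spaced")
  mvts(as.matrix(d[setdiff(names(d), "time")]), sampling_interval = dt[1],
       meta = meta)
}

#' Noise specification for the stochastic simulator
#'
#' @param mode `"additive"` (constant amplitude) or `"multiplicative"`
#'   (amplitude proportional to the current abundance).
#' @param sigma Wiener-process scale per variable (default 0.02).
#' @param measurement_sd Standard deviation of i.i.d. Gaussian observational
#'   noise added after simulation (0 = none).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("additive", "multiplicative"), sigma = 0.02,
                       measurement_sd = 0) {
  mode <- match.arg(mode)
  if (any(sigma < 0) || measurement_sd < 0)
    stop_parameter("sigma and measurement_sd must be >= 0")
  structure(list(mode = mode, sigma = sigma,
                 measurement_sd = measurement_sd), class = "noise_spec")
}

#' Stochastic integration of the plant-pollinator model
#'
#' Euler-Maruyama scheme: `x <- x + drift * dt + amp * sqrt(dt) * Z` with
#' `amp = sigma` (additive) or `sigma * x` (multiplicative) and independent
#' standard normal `Z` per variable and step. Abundances are clipped at zero
#' after every step; the burn-in segment is discarded and rows are recorded
#' every `sampling_interval` time units.
#'
#' @param params A [pp_params()] object.
#' @param start Initial state (typically an equilibrium).
#' @param noise A [noise_spec()]; its `sigma` overrides the per-species
#'   scales in `params` when not `NULL`.
#' @param duration Recorded length in time units (`duration /
#'   sampling_interval` rows).
#' @param dt Integration step (default 0.01).
#' @param sampling_interval Time between recorded rows; must be an integer
#'   multiple of `dt`.
#' @param burn_in Time discarded before recording starts.
#' @param seed Integer seed (bit-reproducible across calls).
#' @param stream Sub-stream index, used to split one master seed into
#'   independent per-step streams.
#' @return An [mvts()] with attributes in `meta` (seed, clipping count).
#' @export
simulate_series <- function(params, start, noise = noise_spec(),
                            duration, dt = 0.01, sampling_interval = 0.1,
                            burn_in = 100, seed = 1L, stream = 0L) {
  check_state(start, params)
  if (dt <= 0 || sampling_interval < dt)
    stop_parameter("need 0 < dt <= sampling_interval")
  record_every <- round(sampling_interval / dt)
  if (abs(record_every * dt - sampling_interval) > 1e-9 * sampling_interval)
    stop_parameter("sampling_interval must be an integer multiple of dt")
  n_record <- round(duration / sampling_interval)
  if (n_record < 2) stop_parameter("requested length is below 2 samples")
  sigma <- if (is.null(noise$sigma)) c(params$sigma_A, params$sigma_P) else
    rep_len(noise$sigma, params$S_A + params$S_P)

  vals <- em_integrate_cpp(
    params$r_A, params$r_P, params$gamma_A, params$gamma_P,
    params$c_A, params$c_P, params$h_A, params$h_P,
    sigma, identical(noise$mode, "multiplicative"),
    as.numeric(start), dt, as.integer(n_record), as.integer(record_every),
    as.integer(round(burn_in / dt)), as.double(seed), as.double(stream))

  n_clipped <- attr(vals, "n_clipped")
  attr(vals, "n_clipped") <- NULL
  labels <- c(paste0("A", seq_len(params$S_A)), paste0("P", seq_len(params$S_P)))
  mvts(vals, sampling_interval, labels,
       meta = list(seed = seed, stream = stream, noise_mode = noise$mode,
                   n_clipped = n_clipped,
                   n_steps_total = (n_record * record_every +
                                      round(burn_in / dt))))
}

#' Add i.i.d. Gaussian measurement noise
#'
#' Pure transform: returns a copy with `N(0, sd^2)` added element-wise.
#'
#' @param ts An [mvts()].
#' @param sd Measurement noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @export
add_measurement_noise <- function(ts, sd, seed = 1L) {
  stopifnot(inherits(ts, "mvts"))
  if (sd < 0) stop_parameter("sd must be >= 0")
  if (sd == 0) return(ts)
  vals <- ts$values + with_private_seed(seed, {
    matrix(stats::rnorm(length(ts$values), 0, sd), nrow(ts$values))
  })
  out <- ts
  out$values <- vals
  out$meta$measurement_sd <- sd
  out
}

#' Truncate a series to its first n samples
#' @param ts An [mvts()].
#' @param n Number of rows to keep (`2 <= n <= T`).
#' @export
truncate_length <- function(ts, n) {
  stopifnot(inherits(ts, "mvts"))
  if (n > nrow(ts$values)) stop_parameter("n exceeds the series length")
  if (n < 2) stop_parameter("n must be >= 2")
  out <- ts
  out$values <- ts$values[seq_len(n), , drop = FALSE]
  out
}

#' Thin a series to every factor-th sample
#'
#' Keeps rows `1, 1+factor, 1+2*factor, ...` and multiplies the sampling
#' interval accordingly. Post-hoc alternative to integrating longer at a
#' coarser recording interval.
#'
#' @param ts An [mvts()].
#' @param factor Positive integer thinning factor.
#' @export
thin_resolution <- function(ts, factor) {
  stopifnot(inherits(ts, "mvts"))
  factor <- as.integer(factor)
  if (factor < 1) stop_parameter("factor must be >= 1")
  if (factor == 1) return(ts)
  keep <- seq(1, nrow(ts$values), by = factor)
  if (length(keep) < 2) stop_parameter("thinning leaves fewer than 2 rows")
  out <- ts
  out$values <- ts$values[keep, , drop = FALSE]
  out$sampling_interval <- ts$sampling_interval * factor
  out
}

#' Select a subset of observed variables
#' @param ts An [mvts()].
#' @param indices Unique column indices to keep.
#' @export
select_subset <- function(ts, indices) {
  stopifnot(inherits(ts, "mvts"))
  if (length(indices) < 1 || anyDuplicated(indices))
    stop_parameter("indices must be non-empty and unique")
  if (any(indices < 1 | indices > ncol(ts$values)))
    stop_parameter("subset index out of range")
  out <- ts
  out$values <- ts$values[, indices, drop = FALSE]
  out$labels <- ts$labels[indices]
  out
}

#' Generate stationary time series along a bifurcation sweep
#'
#' For every step of a stability sweep, integrates the stochastic model from
#' that step's equilibrium (after burn-in) and packages the series together
#' with the true stability metrics. Per-step seeds are derived
#' deterministically from the master seed, so two scenarios sharing a master
#' seed see identical latent sample paths wherever their settings agree.
#'
#' @param sweep A [sweep_stability()] result.
#' @param noise A [noise_spec()].
#' @param length Number of recorded samples per step.
#' @param sampling_interval Time between samples.
#' @param seed Master integer seed.
#' @param dt Integration step.
#' @param burn_in Burn-in time per step.
#' @param extinction_threshold Sustained-crossing threshold used to flag
#'   realized collapses (a step whose final 5% of samples stay below the
#'   threshold in any variable is excluded with a warning).
#' @return Object of class `sweep_series`: list with `series` (list of
#'   [mvts()]), `summary` (per-step bifurcation parameter and metrics),
#'   `excluded` (flagged step indices), `seed`.
#' @export
generate_sweep_series <- function(sweep, noise = noise_spec(), length = 10000,
                                  sampling_interval = 0.1, seed = 1L,
                                  dt = 0.01, burn_in = 100,
                                  extinction_threshold = 0.1) {
  stopifnot(inherits(sweep, "pp_sweep"))
  n_steps <- base::length(sweep$steps)
  series <- vector("list", n_steps)
  excluded <- integer(0)
  for (s in seq_len(n_steps)) {
    st <- sweep$steps[[s]]
    ts <- simulate_series(st$params, st$state, noise,
                          duration = length * sampling_interval,
                          dt = dt, sampling_interval = sampling_interval,
                          burn_in = burn_in, seed = seed, stream = s)
    ts$meta$step <- s
    ts$meta$eigenvalue <- st$metrics$dominant_eigenvalue
    tail_rows <- seq.int(max(1, floor(0.95 * nrow(ts$values))),
                         nrow(ts$values))
    # a variable whose equilibrium already sits below the threshold is not a
    # realized collapse; compare each path against its own equilibrium
    at_risk <- st$state >= extinction_threshold
    if (any(at_risk & apply(ts$values[tail_rows, , drop = FALSE] <
                              extinction_threshold, 2, all))) {
      warning("realized path crossed into collapse at sweep step ", s,
              "; step flagged and excluded")
      excluded <- c(excluded, s)
    }
    series[[s]] <- ts
  }
  structure(list(series = series, summary = sweep$summary,
                 excluded = excluded, seed = seed,
                 sampling_interval = sampling_interval),
            class = "sweep_series")
}

#' @export
print.sweep_series <- function(x, ...) {
  n <- length(x$series)
  cat(sprintf("sweep_series: %d steps x (%d samples x %d variables)\n",
              n, nrow(x$series[[1]]$values), ncol(x$series[[1]]$values)))
  cat(sprintf("  eigenvalue %.3f -> %.3f | %d excluded step(s)\n",
              x$summary$eigenvalue[1], x$summary$eigenvalue[n],
              length(x$excluded)))
  invisible(x)
}

#' @export
summary.sweep_series <- function(object, ...) {
  s <- object$summary
  s$excluded <- s$step %in% object$excluded
  s
}
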