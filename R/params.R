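#' Construct a parameter set for the plant-pollinator model
#'
#' Bundles all parameters of the bipartite facilitation-competition model:
#' per-capita growth rates, saturating mutualistic gains, within-guild
#' competition, half-saturation constants and noise scales. The state vector
#' convention everywhere in the package is pollinators first, then plants.
#'
#' @param r_A,r_P Per-capita growth rates (per time unit) of the `S_A`
#'   pollinators and `S_P` plants. May be negative (obligate mutualists).
#' @param gamma_A `S_A x S_P` matrix of mutualistic gains of pollinators from
#'   plants; `gamma_P` is the `S_P x S_A` counterpart for plants.
#' @param c_A,c_P Within-guild competition matrices (`S_A x S_A` and
#'   `S_P x S_P`). Intraspecific competition (the diagonal) must exceed
#'   interspecific competition row-wise.
#' @param h_A,h_P Half-saturation constants of the mutualistic functional
#'   response; scalars are recycled.
#' @param sigma_A,sigma_P Noise scales per species; scalars are recycled.
#' @return An object of class `pp_params`.
#' @examples
#' p <- params_4d()
#' p$gamma_A
#' @export
pp_params <- function(r_A, r_P, gamma_A, gamma_P, c_A, c_P,
                      h_A = 0.5, h_P = 0.5, sigma_A = 0.02, sigma_P = 0.02) {
  S_A <- length(r_A)
  S_P <- length(r_P)
  gamma_A <- as.matrix(gamma_A)
  gamma_P <- as.matrix(gamma_P)
  c_A <- as.matrix(c_A)
  c_P <- as.matrix(c_P)
  h_A <- rep_len(as.numeric(h_A), S_A)
  h_P <- rep_len(as.numeric(h_P), S_P)
  sigma_A <- rep_len(as.numeric(sigma_A), S_A)
  sigma_P <- rep_len(as.numeric(sigma_P), S_P)

  if (!identical(dim(gamma_A), c(S_A, S_P)))
    stop_dimension("gamma_A must be S_A x S_P (", S_A, " x ", S_P, ")")
  if (!identical(dim(gamma_P), c(S_P, S_A)))
    stop_dimension("gamma_P must be S_P x S_A (", S_P, " x ", S_A, ")")
  if (!identical(dim(c_A), c(S_A, S_A)))
    stop_dimension("c_A must be S_A x S_A")
  if (!identical(dim(c_P), c(S_P, S_P)))
    stop_dimension("c_P must be S_P x S_P")
  nonneg <- c(gamma_A, gamma_P, c_A, c_P, h_A, h_P, sigma_A, sigma_P)
  if (any(!is.finite(c(r_A, r_P, nonneg))))
    stop_precondition("all parameters must be finite")
  if (any(nonneg < 0))
    stop_precondition("gamma, c, h and sigma entries must be >= 0")
  check_self_competition(c_A, "c_A")
  check_self_competition(c_P, "c_P")

  structure(
    list(S_A = S_A, S_P = S_P, r_A = as.numeric(r_A), r_P = as.numeric(r_P),
         gamma_A = gamma_A, gamma_P = gamma_P, c_A = c_A, c_P = c_P,
         h_A = h_A, h_P = h_P, sigma_A = sigma_A, sigma_P = sigma_P),
    class = "pp_params"
  )
}

check_self_competition <- function(cm, name) {
  S <- nrow(cm)
  if (S < 2) return(invisible(TRUE))
  for (k in seq_len(S)) {
    if (any(cm[k, -k] >= cm[k, k]))
      stop_precondition(
        "intraspecific competition must exceed interspecific competition ",
        "row-wise in ", name)
  }
  invisible(TRUE)
}

#' Default 4-species (2 plants, 2 pollinators) parameter set
#'
#' The two guilds are mirror images: within-pair mutualism 1, cross-pair 0.8,
#' self-competition 0.3, cross-competition 0.1 and half-saturation 0.5 for
#' every species. The plant growth rate selects the regime: `r_P = -0.5`
#' gives a non-reactive (locally gradient-like) equilibrium, `r_P = 2.2` an
#' equilibrium that turns reactive as the bifurcation is approached.
#'
#' @param reactive Logical; pick the reactive plant growth-rate tuning.
#' @param r_A Pollinator growth rates (the bifurcation parameter); defaults
#'   to the start of the corresponding bifurcation sweep (see
#'   [default_sweep_4d()]).
#' @param sigma Noise scale applied to all species.
#' @return A `pp_params` object.
#' @export
params_4d <- function(reactive = FALSE, r_A = NULL, sigma = 0.02) {
  if (is.null(r_A)) r_A <- default_sweep_4d(reactive)$r_A_start
  gam <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  com <- matrix(c(0.3, 0.1, 0.1, 0.3), 2, 2)
  pp_params(r_A = r_A,
            r_P = if (reactive) c(2.2, 2.2) else c(-0.5, -0.5),
            gamma_A = gam, gamma_P = gam, c_A = com, c_P = com,
            h_A = 0.5, h_P = 0.5, sigma_A = sigma, sigma_P = sigma)
}

#' @export
print.pp_params <- function(x, ...) {
  cat("Plant-pollinator model parameters\n")
  cat(sprintf("  %d pollinators, %d plants\n", x$S_A, x$S_P))
  cat("  r_A:", format(x$r_A, digits = 4), "\n")
  cat("  r_P:", format(x$r_P, digits = 4), "\n")
  cat(sprintf("  gamma: within-pair %s | c self %s | h %s | sigma %s\n",
              format(mean(diag(x$gamma_A)), digits = 3),
              format(mean(diag(x$c_A)), digits = 3),
              format(mean(c(x$h_A, x$h_P)), digits = 3),
              format(mean(c(x$sigma_A, x$sigma_P)), digits = 3)))
  invisible(x)
}

#' Serialize a parameter set to a YAML config file
#'
#' @param params A `pp_params` object.
#' @param path Output file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pp_params"))
  flat <- list(
    S_A = params$S_A, S_P = params$S_P,
    r_A = params$r_A, r_P = params$r_P,
    gamma_A = as.numeric(params$gamma_A), gamma_P = as.numeric(params$gamma_P),
    c_A = as.numeric(params$c_A), c_P = as.numeric(params$c_P),
    h_A = params$h_A, h_P = params$h_P,
    sigma_A = params$sigma_A, sigma_P = params$sigma_P
  )
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' Read a parameter set from a YAML config file
#'
#' @param path File written by [write_params()].
#' @return A `pp_params` object.
#' @export
read_params <- function(path) {
  f <- yaml::read_yaml(path)
  pp_params(
    r_A = f$r_A, r_P = f$r_P,
    gamma_A = matrix(f$gamma_A, f$S_A, f$S_P),
    gamma_P = matrix(f$gamma_P, f$S_P, f$S_A),
    c_A = matrix(f$c_A, f$S_A, f$S_A),
    c_P = matrix(f$c_P, f$S_P, f$S_P),
    h_A = f$h_A, h_P = f$h_P, sigma_A = f$sigma_A, sigma_P = f$sigma_P
  )
}

# -- classed error helpers ----------------------------------------------------

stop_classed <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "ewsbench_error")))
}
stop_dimension <- function(...) stop_classed("ewsbench_dimension_error", ...)
stop_precondition <- function(...) stop_classed("ewsbench_precondition_error", ...)
stop_parameter <- function(...) stop_classed("ewsbench_parameter_error", ...)
stop_convergence <- function(...) stop_classed("ewsbench_convergence_error", ...)
stop_sweep <- function(...) stop_classed("ewsbench_sweep_error", ...)
stop_degenerate <- function(...) stop_classed("ewsbench_degenerate_error", ...)
stop_catalogue <- function(...) stop_classed("ewsbench_catalogue_error", ...)
stop_search <- function(...) stop_classed("ewsbench_search_error", ...)
stop_evaluation <- function(...) stop_classed("ewsbench_evaluation_error", ...)

# run code with a private RNG stream, leaving the caller's RNG state intact
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic 31-bit sub-seed from a master seed and stream indices
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}
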