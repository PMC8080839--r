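#' Deterministic drift of the plant-pollinator model
#'
#' Evaluates the deterministic part of the stochastic model at a state:
#' for each species, (growth + saturating mutualism - competition) times its
#' own abundance. The origin is absorbing, so the drift there is exactly zero.
#'
#' @param state Non-negative abundance vector, pollinators first then plants
#'   (length `S_A + S_P`).
#' @param params A [pp_params()] object.
#' @return Numeric vector of abundance rates of change (per time unit).
#' @examples
#' p <- params_4d()
#' model_drift(rep(1, 4), p)
#' @export
model_drift <- function(state, params) {
  check_state(state, params)
  A <- state[seq_len(params$S_A)]
  P <- state[params$S_A + seq_len(params$S_P)]
  gA <- as.vector(params$gamma_A %*% P)
  gP <- as.vector(params$gamma_P %*% A)
  dA <- A * (params$r_A + gA / (1 + params$h_A * gA) -
               as.vector(params$c_A %*% A))
  dP <- P * (params$r_P + gP / (1 + params$h_P * gP) -
               as.vector(params$c_P %*% P))
  c(dA, dP)
}

check_state <- function(state, params) {
  if (!inherits(params, "pp_params"))
    stop_precondition("params must be a pp_params object")
  if (length(state) != params$S_A + params$S_P)
    stop_dimension("state has length ", length(state), ", expected ",
                   params$S_A + params$S_P)
  if (any(!is.finite(state)))
    stop_precondition("state must be finite")
  if (any(state < 0))
    stop_precondition("state must be non-negative")
  invisible(TRUE)
}

#' Analytic Jacobian of the model drift
#'
#' Partial derivatives of [model_drift()] with respect to the abundances.
#' The saturating mutualism term g/(1+h*g) contributes the derivative
#' 1/(1+h*g)^2 through the gamma-weighted partner sum.
#'
#' @inheritParams model_drift
#' @return A `(S_A+S_P) x (S_A+S_P)` matrix.
#' @export
model_jacobian <- function(state, params) {
  check_state(state, params)
  SA <- params$S_A
  SP <- params$S_P
  A <- state[seq_len(SA)]
  P <- state[SA + seq_len(SP)]
  gA <- as.vector(params$gamma_A %*% P)
  gP <- as.vector(params$gamma_P %*% A)
  satA <- gA / (1 + params$h_A * gA)
  satP <- gP / (1 + params$h_P * gP)
  dsatA <- 1 / (1 + params$h_A * gA)^2
  dsatP <- 1 / (1 + params$h_P * gP)^2
  phiA <- params$r_A + satA - as.vector(params$c_A %*% A)
  phiP <- params$r_P + satP - as.vector(params$c_P %*% P)

  J_AA <- diag(phiA, SA) - A * params$c_A
  J_AP <- (A * dsatA) * params$gamma_A
  J_PP <- diag(phiP, SP) - P * params$c_P
  J_PA <- (P * dsatP) * params$gamma_P
  rbind(cbind(J_AA, J_AP), cbind(J_PA, J_PP))
}

#' Find a non-negative equilibrium of the deterministic model
#'
#' Damped Newton iteration on the drift, with a fallback to long deterministic
#' relaxation (forward Euler with clipping at zero) when Newton stalls or
#' leaves the non-negative orthant. Tiny negative entries in a converged
#' solution are projected to zero and the residual re-verified.
#'
#' @param params A [pp_params()] object.
#' @param initial_guess Non-negative starting state (default all ones).
#' @param tol Convergence tolerance on `max(abs(drift))`.
#' @param max_iter Newton iteration budget.
#' @return An equilibrium state vector (attribute `residual` carries the
#'   final drift norm).
#' @examples
#' # one-species logistic limit: equilibrium at r/c
#' p <- pp_params(r_A = 0.3, r_P = -0.1, gamma_A = matrix(0, 1, 1),
#'                gamma_P = matrix(0, 1, 1), c_A = matrix(0.3, 1, 1),
#'                c_P = matrix(0.3, 1, 1))
#' find_equilibrium(p, c(0.5, 0))[1]
#' @export
find_equilibrium <- function(params, initial_guess = NULL, tol = 1e-10,
                             max_iter = 100L) {
  S <- params$S_A + params$S_P
  x <- if (is.null(initial_guess)) rep(1, S) else as.numeric(initial_guess)
  if (length(x) != S) stop_dimension("initial_guess has wrong length")
  if (any(x < 0)) stop_precondition("initial_guess must be non-negative")

  res <- newton_solve(x, params, tol, max_iter)
  if (!res$converged) {
    # relaxation fallback: integrate the deterministic flow, then retry Newton
    xr <- relax_state(res$x, params, duration = 2000, dt = 0.01)
    res2 <- newton_solve(xr, params, tol, max_iter)
    if (res2$converged) res <- res2
  }
  if (!res$converged)
    stop_convergence("equilibrium search did not converge; best residual ",
                     format(res$residual, digits = 4))
  x <- res$x
  if (any(x < 0)) {
    if (any(x < -1e-6))
      stop_convergence("converged to a state with a negative abundance")
    x[x < 0] <- 0
    if (max(abs(model_drift(x, params))) > max(tol, 1e-8))
      stop_convergence("projection to the non-negative orthant broke the ",
                       "equilibrium")
  }
  structure(x, residual = max(abs(model_drift(x, params))))
}

newton_solve <- function(x, params, tol, max_iter) {
  f <- model_drift(pmax(x, 0), params)
  best <- max(abs(f))
  x <- pmax(x, 0)
  for (it in seq_len(max_iter)) {
    f <- model_drift(x, params)
    r0 <- max(abs(f))
    if (r0 < tol) return(list(x = x, converged = TRUE, residual = r0))
    J <- model_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, converged = FALSE, residual = r0))
    alpha <- 1
    repeat {
      xn <- x - alpha * step
      rn <- if (any(!is.finite(xn))) Inf else
        max(abs(model_drift(pmax(xn, 0), params)))
      if (rn < r0 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (!(rn < r0)) return(list(x = x, converged = FALSE, residual = r0))
    x <- pmax(xn, 0)
    best <- min(best, rn)
  }
  r <- max(abs(model_drift(x, params)))
  list(x = x, converged = r < tol, residual = r)
}

relax_state <- function(x, params, duration = 500, dt = 0.01) {
  n <- max(1L, as.integer(ceiling(duration / dt)))
  # noiseless run of the stochastic integrator: same clipped Euler flow
  out <- tryCatch(
    em_integrate_cpp(params$r_A, params$r_P, params$gamma_A, params$gamma_P,
                     params$c_A, params$c_P, params$h_A, params$h_P,
                     rep(0, length(x)), FALSE, as.numeric(x), dt, 1L, n, 0L,
                     0, 0),
    error = function(e) stop_convergence("relaxation diverged: ",
                                         conditionMessage(e)))
  as.numeric(out[1, ])
}

#' Linear stability and reactivity at a state
#'
#' Computes the dominant eigenvalue of the Jacobian (largest real part; the
#' asymptotic recovery rate, negated) and the reactivity (largest eigenvalue
#' of the Hermitian part `(J + t(J))/2`; positive values mean perturbations
#' can grow transiently even at a stable equilibrium).
#'
#' @inheritParams model_drift
#' @param check_equilibrium Warn if the drift residual at `state` exceeds
#'   `1e-6` (the metrics are then not equilibrium stability metrics).
#' @return A list of class `stability_metrics` with elements
#'   `dominant_eigenvalue`, `reactivity`, `is_stable`, `is_reactive`,
#'   `residual`.
#' @export
stability_metrics <- function(params, state, check_equilibrium = TRUE) {
  check_state(state, params)
  residual <- max(abs(model_drift(state, params)))
  if (check_equilibrium && residual > 1e-6)
    warning("state is not an equilibrium (residual ",
            format(residual, digits = 3), "); metrics are not equilibrium ",
            "stability metrics")
  J <- model_jacobian(state, params)
  lam <- max(Re(eigen(J, only.values = TRUE)$values))
  react <- max(eigen((J + t(J)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values)
  structure(list(dominant_eigenvalue = lam, reactivity = react,
                 is_stable = lam < 0, is_reactive = react > 0,
                 residual = residual),
            class = "stability_metrics")
}

#' @export
print.stability_metrics <- function(x, ...) {
  cat(sprintf("dominant eigenvalue %.4f (%s), reactivity %.4f (%s)\n",
              x$dominant_eigenvalue, if (x$is_stable) "stable" else "unstable",
              x$reactivity, if (x$is_reactive) "reactive" else "non-reactive"))
  invisible(x)
}

#' Continue the interior equilibrium along a bifurcation-parameter sweep
#'
#' Interpolates the pollinator growth rates `r_A` linearly between two
#' endpoints in `n_steps` steps and tracks the interior equilibrium by
#' warm-starting each Newton solve from the previous step, staying on a single
#' branch. Stability metrics are recorded at every step.
#'
#' @param params Model parameters; `r_A` is overridden along the sweep.
#' @param r_A_start,r_A_end Endpoint values of the bifurcation parameter.
#' @param n_steps Number of sweep steps (default 50).
#' @param initial_guess Starting state for the first equilibrium.
#' @return An object of class `pp_sweep`: a list with per-step `params`,
#'   `state`, `metrics`, plus a `summary` data frame.
#' @export
sweep_stability <- function(params, r_A_start, r_A_end, n_steps = 50L,
                            initial_guess = NULL) {
  if (length(r_A_start) != params$S_A || length(r_A_end) != params$S_A)
    stop_dimension("sweep endpoints must have length S_A")
  if (n_steps < 1) stop_parameter("n_steps must be >= 1")

  steps <- vector("list", n_steps)
  x <- initial_guess
  for (s in seq_len(n_steps)) {
    t <- if (n_steps == 1) 0 else (s - 1) / (n_steps - 1)
    p_s <- params
    p_s$r_A <- r_A_start + t * (r_A_end - r_A_start)
    if (s == 1 && is.null(x)) {
      x0 <- relax_state(rep(1, params$S_A + params$S_P), p_s, duration = 500)
      x <- tryCatch(find_equilibrium(p_s, x0),
                    error = function(e) stop_sweep(
                      "no interior equilibrium at sweep start: ",
                      conditionMessage(e)))
    } else {
      x <- tryCatch(find_equilibrium(p_s, x),
                    error = function(e) stop_sweep(
                      "equilibrium lost at sweep step ", s, ": ",
                      conditionMessage(e)))
    }
    if (min(x) < 1e-4)
      stop_sweep("interior equilibrium collapsed at sweep step ", s)
    m <- stability_metrics(p_s, x)
    if (!m$is_stable)
      stop_sweep("equilibrium unstable at sweep step ", s,
                 " (dominant eigenvalue ",
                 format(m$dominant_eigenvalue, digits = 3), ")")
    steps[[s]] <- list(params = p_s, state = as.numeric(x), metrics = m)
  }
  summary <- data.frame(
    step = seq_len(n_steps),
    t(vapply(steps, function(z) z$params$r_A, numeric(params$S_A))),
    eigenvalue = vapply(steps, function(z) z$metrics$dominant_eigenvalue, 0),
    reactivity = vapply(steps, function(z) z$metrics$reactivity, 0)
  )
  names(summary)[1 + seq_len(params$S_A)] <- paste0("r_A", seq_len(params$S_A))
  structure(list(steps = steps, summary = summary,
                 r_A_start = r_A_start, r_A_end = r_A_end),
            class = "pp_sweep")
}

#' @export
print.pp_sweep <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("Bifurcation sweep: %d steps\n", n))
  cat(sprintf("  r_A: [%s] -> [%s]\n",
              paste(format(x$r_A_start, digits = 3), collapse = ", "),
              paste(format(x$r_A_end, digits = 3), collapse = ", ")))
  cat(sprintf("  dominant eigenvalue: %.4f -> %.4f\n",
              x$summary$eigenvalue[1], x$summary$eigenvalue[n]))
  cat(sprintf("  reactivity:          %.4f -> %.4f\n",
              x$summary$reactivity[1], x$summary$reactivity[n]))
  invisible(x)
}

#' @export
plot.pp_sweep <- function(x, ...) {
  s <- x$summary
  graphics::matplot(s$step, cbind(s$eigenvalue, s$reactivity), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "sweep step", ylab = "per time unit", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("dominant eigenvalue", "reactivity"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Default 4D bifurcation sweep endpoints
#'
#' Both tunings are calibrated so the dominant Jacobian eigenvalue of the
#' tracked interior equilibrium moves from -0.45 to -0.15 along the sweep,
#' which makes the loss of resilience identical between the reactive and
#' non-reactive regimes. For the reactive tuning this corresponds to
#' `r_A` from (-0.91, -0.81) to (-1.45, -1.35); for the non-reactive tuning
#' the endpoints are found numerically (keeping the fixed offset
#' `r_A2 = r_A1 + 0.1`) because no closed form is available.
#'
#' @param reactive Logical; reactive or non-reactive tuning.
#' @return List with `r_A_start` and `r_A_end` (each length 2).
#' @export
default_sweep_4d <- function(reactive = FALSE) {
  if (reactive) {
    return(list(r_A_start = c(-0.91, -0.81), r_A_end = c(-1.45, -1.35)))
  }
  cal <- sweep_calibration_cache()
  list(r_A_start = cal$start, r_A_end = cal$end)
}

# memoised numeric calibration of the non-reactive sweep endpoints
.ewsbench_cache <- new.env(parent = emptyenv())

sweep_calibration_cache <- function() {
  if (!is.null(.ewsbench_cache$nonreactive_sweep))
    return(.ewsbench_cache$nonreactive_sweep)
  cal <- calibrate_sweep_4d(reactive = FALSE,
                            eigenvalue_start = -0.45, eigenvalue_end = -0.15)
  .ewsbench_cache$nonreactive_sweep <- cal
  cal
}

#' Calibrate 4D sweep endpoints to target eigenvalues
#'
#' Finds the values of the bifurcation parameter `r_A = (a, a + 0.1)` at which
#' the dominant Jacobian eigenvalue of the interior equilibrium equals the
#' requested start and end values, by root finding along an equilibrium
#' continuation.
#'
#' @param reactive Logical tuning flag.
#' @param eigenvalue_start,eigenvalue_end Target dominant eigenvalues.
#' @return List with `start` and `end` r_A vectors.
#' @export
calibrate_sweep_4d <- function(reactive = FALSE, eigenvalue_start = -0.45,
                               eigenvalue_end = -0.15) {
  base <- params_4d(reactive = reactive, r_A = c(-0.3, -0.2))
  anchor <- find_equilibrium(
    base, relax_state(rep(1, 4), base, duration = 500))

  lam_at <- function(a) {
    # short continuation from the anchor keeps us on the interior branch
    x <- anchor
    path <- seq(-0.3, a, length.out = max(2L, ceiling(abs(a + 0.3) / 0.02)))
    for (ai in path) {
      p <- base
      p$r_A <- c(ai, ai + 0.1)
      x <- find_equilibrium(p, x)
    }
    p <- base
    p$r_A <- c(a, a + 0.1)
    stability_metrics(p, x)$dominant_eigenvalue
  }

  a_start <- stats::uniroot(function(a) lam_at(a) - eigenvalue_start,
                            interval = c(-0.4, -0.1), tol = 1e-8)$root
  a_end <- stats::uniroot(function(a) lam_at(a) - eigenvalue_end,
                          interval = c(-0.66, -0.4), tol = 1e-8)$root
  list(start = c(a_start, a_start + 0.1), end = c(a_end, a_end + 0.1))
}

#' @export
summary.pp_sweep <- function(object, ...) object$summary
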