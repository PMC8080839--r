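#' Random search for high-dimensional collapse parameterizations
#'
#' Draws random parameter sets for an `S_A x S_P` network (default 10 + 10)
#' and accepts the first one for which (a) the system has a stable interior
#' equilibrium with every abundance above 0.1, (b) decreasing the growth rate
#' of the driven pollinators pushes the system through a bifurcation, and (c)
#' the deterministic continuation past the bifurcation ends in the requested
#' collapse: `"full"` (all species extinct) or `"partial"` (exactly the driven
#' pollinators extinct, every other species persisting).
#'
#' Fixed structure, shared with the 4-species default: half-saturation 0.5,
#' self-competition 0.3 and within-pair mutualism 1 (pollinator k paired with
#' plant k). Free entries are drawn uniformly: cross-pair mutualism on
#' (0, 0.3), cross-competition on (0.02, 0.12), plant growth rates on
#' (-0.35, -0.05) for full collapse or (-0.15, 0.1) for partial collapse, and
#' pollinator growth rates on (-0.25, -0.05). For a partial collapse only
#' pollinators 1 to `ceiling(S_A/2)` are driven.
#'
#' @param dims Integer pair `(S_A, S_P)`.
#' @param collapse_type `"full"` or `"partial"`.
#' @param seed Integer seed; the same seed and budget return the same set.
#' @param budget Maximum number of random draws.
#' @param extinction_threshold Abundance below which a species counts as
#'   extinct (also the coexistence criterion at the start).
#' @return List of class `pp_search_result`: `params` (at the sweep start),
#'   `r_A_start`, `r_A_end`, `driven` (indices of driven pollinators),
#'   `final_state` (post-bifurcation attractor), `eigenvalue_start`,
#'   `eigenvalue_end`, `attempts`.
#' @export
random_parameter_search <- function(dims = c(10L, 10L),
                                    collapse_type = c("full", "partial"),
                                    seed = 1L, budget = 200L,
                                    extinction_threshold = 0.1) {
  collapse_type <- match.arg(collapse_type)
  SA <- as.integer(dims[1])
  SP <- as.integer(dims[2])
  if (SA < 2 || SP < 2) stop_parameter("dims must both be >= 2")
  driven <- if (collapse_type == "full") seq_len(SA) else
    seq_len(ceiling(SA / 2))

  fails <- c(no_interior = 0L, no_bifurcation = 0L, wrong_collapse = 0L)
  result <- with_private_seed(seed, {
    out <- NULL
    for (attempt in seq_len(budget)) {
      params <- draw_candidate(SA, SP, collapse_type)
      cand <- try_candidate(params, driven, extinction_threshold)
      if (!is.null(cand$fail)) {
        fails[cand$fail] <- fails[cand$fail] + 1L
        next
      }
      out <- c(cand, list(attempts = attempt))
      break
    }
    out
  })
  if (is.null(result))
    stop_search("random search budget exhausted (", budget, " draws): ",
                paste(names(fails), fails, sep = "=", collapse = ", "))
  structure(c(result, list(collapse_type = collapse_type, driven = driven,
                           seed = seed)),
            class = "pp_search_result")
}

draw_candidate <- function(SA, SP, collapse_type) {
  # off-diagonal interaction strengths scale roughly with 1/(number of
  # partners) so total cross-guild input stays comparable to the 4-species
  # tuning; competition stays dominated by the self term
  gA <- matrix(stats::runif(SA * SP, 0.02, 0.2), SA, SP)
  gP <- matrix(stats::runif(SP * SA, 0.02, 0.2), SP, SA)
  npair <- min(SA, SP)
  gA[cbind(seq_len(npair), seq_len(npair))] <- 1
  gP[cbind(seq_len(npair), seq_len(npair))] <- 1
  cA <- matrix(stats::runif(SA * SA, 0.005, 0.04), SA, SA)
  cP <- matrix(stats::runif(SP * SP, 0.005, 0.04), SP, SP)
  diag(cA) <- 0.3
  diag(cP) <- 0.3
  r_P <- if (collapse_type == "full") stats::runif(SP, -0.35, -0.05) else
    stats::runif(SP, -0.15, 0.1)
  r_A <- stats::runif(SA, -0.25, -0.05)
  pp_params(r_A = r_A, r_P = r_P, gamma_A = gA, gamma_P = gP,
            c_A = cA, c_P = cP, h_A = 0.5, h_P = 0.5)
}

try_candidate <- function(params, driven, thr, delta = 0.02,
                          max_drive = 3) {
  S <- params$S_A + params$S_P
  x <- tryCatch(
    find_equilibrium(params, relax_state(rep(1, S), params, duration = 300)),
    error = function(e) NULL)
  if (is.null(x) || min(x) <= thr) return(list(fail = "no_interior"))
  m <- stability_metrics(params, x)
  if (!m$is_stable) return(list(fail = "no_interior"))
  lam_start <- m$dominant_eigenvalue

  # drive the selected pollinators down until the interior branch is lost
  r0 <- params$r_A
  p <- params
  x_prev <- x
  r_prev <- r0
  lam_prev <- lam_start
  r_end <- NULL       # last step comfortably below zero (lambda <= -0.02)
  lam_end <- NA_real_
  found <- FALSE
  n_steps <- ceiling(max_drive / delta)
  for (s in seq_len(n_steps)) {
    p$r_A[driven] <- r0[driven] - s * delta
    x_new <- tryCatch(find_equilibrium(p, x_prev), error = function(e) NULL)
    lam <- if (is.null(x_new)) NA_real_ else
      stability_metrics(p, x_new, check_equilibrium = FALSE)$dominant_eigenvalue
    if (is.null(x_new) || min(x_new) < 0.02 || lam >= -0.005) {
      found <- TRUE
      break
    }
    x_prev <- x_new
    r_prev <- p$r_A
    lam_prev <- lam
    if (lam <= -0.02) {
      r_end <- p$r_A
      lam_end <- lam
    }
  }
  if (!found || is.null(r_end) || lam_end <= lam_start + 1e-6)
    return(list(fail = "no_bifurcation"))

  # classify the post-bifurcation attractor from slightly past the fold
  p_post <- params
  p_post$r_A <- r_prev
  p_post$r_A[driven] <- r_prev[driven] - 5 * delta
  x_post <- relax_state(x_prev, p_post, duration = 3000, dt = 0.02)
  extinct <- which(x_post < thr)
  ok <- if (length(driven) == params$S_A) {
    length(extinct) == length(x_post)  # full network collapse
  } else {
    setequal(extinct, driven)          # exactly the driven pollinators
  }
  if (!ok) return(list(fail = "wrong_collapse"))

  # the sweep ends near, but strictly below, zero
  list(params = params, r_A_start = r0, r_A_end = r_end,
       start_state = as.numeric(x), final_state = x_post,
       eigenvalue_start = lam_start, eigenvalue_end = lam_end)
}

#' @export
print.pp_search_result <- function(x, ...) {
  cat(sprintf("Accepted %s-collapse parameter set (%d pollinators, %d plants)\n",
              x$collapse_type, x$params$S_A, x$params$S_P))
  cat(sprintf("  attempts: %d | driven pollinators: %s\n", x$attempts,
              paste(x$driven, collapse = ",")))
  cat(sprintf("  sweep eigenvalue: %.3f -> %.3f\n",
              x$eigenvalue_start, x$eigenvalue_end))
  cat(sprintf("  post-bifurcation survivors: %d of %d\n",
              sum(x$final_state >= 0.1), length(x$final_state)))
  invisible(x)
}
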