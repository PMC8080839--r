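# shared fixtures: tiny parameter sets and reference generators

# single species with logistic self-limitation (mutualism off); the plant is
# decoupled and kept at zero
logistic_params <- function(r = 0.3, c = 0.3, sigma = 0.02) {
  pp_params(r_A = r, r_P = -0.1,
            gamma_A = matrix(0, 1, 1), gamma_P = matrix(0, 1, 1),
            c_A = matrix(c, 1, 1), c_P = matrix(0.3, 1, 1),
            sigma_A = sigma, sigma_P = sigma)
}

# 1 pollinator + 1 plant with explicit entries
pair_params <- function(r_A, r_P, gamma = 0, c_self = 0.3, h = 0.5) {
  pp_params(r_A = r_A, r_P = r_P,
            gamma_A = matrix(gamma, 1, 1), gamma_P = matrix(gamma, 1, 1),
            c_A = matrix(c_self, 1, 1), c_P = matrix(c_self, 1, 1),
            h_A = h, h_P = h)
}

random_params_4d <- function(seed) {
  set.seed(seed)
  gA <- matrix(runif(4, 0.2, 1), 2, 2)
  gP <- matrix(runif(4, 0.2, 1), 2, 2)
  cA <- matrix(runif(4, 0, 0.15), 2, 2); diag(cA) <- runif(2, 0.2, 0.4)
  cP <- matrix(runif(4, 0, 0.15), 2, 2); diag(cP) <- runif(2, 0.2, 0.4)
  pp_params(r_A = runif(2, -0.5, 0.2), r_P = runif(2, -0.5, 0.2),
            gamma_A = gA, gamma_P = gP, c_A = cA, c_P = cP,
            h_A = runif(2, 0.2, 1), h_P = runif(2, 0.2, 1))
}

# central finite-difference Jacobian oracle
fd_jacobian <- function(state, params, h = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    J[, j] <- (model_drift(state + e, params) -
                 model_drift(pmax(state - e, 0), params)) / (2 * h)
  }
  J
}

# AR(1) sample path
ar1_series <- function(n, phi, sd = 1, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd))
}

# brute-force tie-corrected Kendall tau over all pairs
kendall_tau_bruteforce <- function(x, y) {
  n <- length(x)
  num <- 0; nx <- 0; ny <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
      num <- num + sx * sy
      nx <- nx + sx^2
      ny <- ny + sy^2
    }
  }
  num / sqrt(nx * ny)
}
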