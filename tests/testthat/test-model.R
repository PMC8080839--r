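test_that("drift matches hand-evaluated cases and absorbs the origin", {
  # origin is absorbing for any parameters
  p <- random_params_4d(1)
  expect_equal(model_drift(rep(0, 4), p), rep(0, 4))

  # growth balanced by self-competition, mutualism off
  p0 <- pair_params(r_A = 0.3, r_P = 0.3, gamma = 0, c_self = 0.3)
  expect_equal(model_drift(c(1, 1), p0), c(0, 0))

  # saturating mutualism: -0.1 + 1/(1 + 0.5*1) - 0.3 = 0.2667 at A = P = 1
  p1 <- pair_params(r_A = -0.1, r_P = -0.1, gamma = 1, c_self = 0.3, h = 0.5)
  expect_equal(model_drift(c(1, 1), p1)[1], -0.1 + 1 / 1.5 - 0.3,
               tolerance = 1e-12)
})

test_that("drift validates dimensions and the positive orthant", {
  p <- random_params_4d(2)
  expect_error(model_drift(rep(1, 3), p), class = "ewsbench_dimension_error")
  expect_error(model_drift(c(-0.1, 1, 1, 1), p),
               class = "ewsbench_precondition_error")
})

test_that("parameter constructor enforces the competition hierarchy", {
  cm <- matrix(c(0.3, 0.35, 0.1, 0.3), 2, 2)  # cross > self in row 1
  expect_error(
    pp_params(r_A = c(-0.1, -0.1), r_P = c(-0.5, -0.5),
              gamma_A = diag(2), gamma_P = diag(2),
              c_A = cm, c_P = matrix(c(0.3, 0.1, 0.1, 0.3), 2, 2)),
    class = "ewsbench_precondition_error")
  expect_error(
    pp_params(r_A = -0.1, r_P = -0.5, gamma_A = matrix(-1, 1, 1),
              gamma_P = matrix(1, 1, 1), c_A = matrix(0.3, 1, 1),
              c_P = matrix(0.3, 1, 1)),
    class = "ewsbench_precondition_error")
})

test_that("analytic Jacobian is diagonal growth at the origin and matches finite differences", {
  p0 <- pair_params(r_A = 0.2, r_P = -0.4, gamma = 0)
  expect_equal(model_jacobian(c(0, 0), p0), diag(c(0.2, -0.4)))

  for (seed in 1:5) {
    p <- random_params_4d(seed)
    set.seed(seed + 100)
    x <- runif(4, 0.2, 3)
    J <- model_jacobian(x, p)
    Jfd <- fd_jacobian(x, p)
    expect_equal(J, Jfd, tolerance = 1e-5)
  }
})

test_that("one-species logistic limit has equilibrium r/c and eigenvalue -r", {
  p <- logistic_params(r = 0.3, c = 0.3)
  eq <- find_equilibrium(p, c(0.5, 0))
  expect_equal(eq[1], 1, tolerance = 1e-8, ignore_attr = TRUE)
  J <- model_jacobian(as.numeric(eq), p)
  expect_equal(J[1, 1], -0.3, tolerance = 1e-8)
})

test_that("extinction is the equilibrium when growth is negative and mutualism off", {
  p <- pair_params(r_A = -0.2, r_P = -0.3, gamma = 0)
  eq <- find_equilibrium(p, c(0.05, 0.05))
  expect_equal(as.numeric(eq), c(0, 0), tolerance = 1e-8)
})

test_that("stability metrics: reactivity bounds the spectral abscissa", {
  # normal (here 1x1) Jacobian: reactivity equals the dominant eigenvalue
  p <- logistic_params(r = 0.3, c = 0.3)
  m <- stability_metrics(p, find_equilibrium(p, c(0.5, 0)))
  expect_equal(m$reactivity, m$dominant_eigenvalue, tolerance = 1e-8)

  for (seed in 1:8) {
    p <- random_params_4d(seed)
    set.seed(seed)
    x <- runif(4, 0.2, 3)
    m <- suppressWarnings(stability_metrics(p, x))
    expect_gte(m$reactivity, m$dominant_eigenvalue - 1e-10)
  }
})

test_that("non-equilibrium states are flagged, not silently accepted", {
  p <- params_4d()
  expect_warning(stability_metrics(p, rep(1, 4)), "not an equilibrium")
})

test_that("4D equilibrium continuation reproduces the calibrated resilience endpoints", {
  rng <- default_sweep_4d(reactive = FALSE)
  sw <- sweep_stability(params_4d(FALSE), rng$r_A_start, rng$r_A_end,
                        n_steps = 10)
  expect_lt(abs(sw$summary$eigenvalue[1] - (-0.45)), 0.01)
  expect_lt(abs(sw$summary$eigenvalue[10] - (-0.15)), 0.01)

  swr <- sweep_stability(params_4d(TRUE), c(-0.91, -0.81), c(-1.45, -1.35),
                         n_steps = 10)
  expect_lt(abs(swr$summary$eigenvalue[1] - (-0.45)), 0.01)
  expect_lt(abs(swr$summary$eigenvalue[10] - (-0.15)), 0.01)
})

test_that("dominant eigenvalue increases monotonically along the sweep", {
  rng <- default_sweep_4d(FALSE)
  sw <- sweep_stability(params_4d(FALSE), rng$r_A_start, rng$r_A_end,
                        n_steps = 25)
  expect_true(all(diff(sw$summary$eigenvalue) > 0))
  expect_true(all(sw$summary$eigenvalue < 0))
})

test_that("degenerate one-step sweep equals a single equilibrium solve", {
  p <- params_4d(FALSE)
  rng <- default_sweep_4d(FALSE)
  sw <- sweep_stability(p, rng$r_A_start, rng$r_A_end, n_steps = 1)
  eq <- find_equilibrium(p, sw$steps[[1]]$state)
  expect_equal(sw$steps[[1]]$state, as.numeric(eq), tolerance = 1e-8)
  expect_equal(nrow(sw$summary), 1)
})

test_that("a sweep that loses the interior branch reports the failing step", {
  # pushing r_A past the fold of the non-reactive branch must error, not
  # silently continue on the extinct branch
  expect_error(
    sweep_stability(params_4d(FALSE), c(-0.3, -0.2), c(-0.9, -0.8),
                    n_steps = 30),
    class = "ewsbench_sweep_error")
})

test_that("reactive tuning becomes reactive near the tipping point, non-reactive does not", {
  swr <- sweep_stability(params_4d(TRUE), c(-0.91, -0.81), c(-1.45, -1.35),
                         n_steps = 20)
  expect_false(swr$steps[[1]]$metrics$is_reactive)
  expect_true(swr$steps[[20]]$metrics$is_reactive)
  expect_true(swr$steps[[20]]$metrics$is_stable)

  rng <- default_sweep_4d(FALSE)
  sw <- sweep_stability(params_4d(FALSE), rng$r_A_start, rng$r_A_end,
                        n_steps = 20)
  expect_false(any(vapply(sw$steps, function(s) s$metrics$is_reactive, TRUE)))
})

test_that("parameter sets roundtrip through the YAML config format", {
  p <- random_params_4d(3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  p2 <- read_params(path)
  expect_equal(p2, p, tolerance = 1e-9)
})
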