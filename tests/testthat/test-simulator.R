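test_that("noiseless integration stays at the equilibrium", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  ts <- simulate_series(p, eq, noise_spec(sigma = 0), duration = 50,
                        burn_in = 10, seed = 1)
  expect_lt(max(abs(sweep(ts$values, 2, eq))), 1e-6)
})

test_that("integration is bit-reproducible under a fixed seed", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  a <- simulate_series(p, eq, duration = 100, seed = 7)
  b <- simulate_series(p, eq, duration = 100, seed = 7)
  c <- simulate_series(p, eq, duration = 100, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  # different seeds share first moments within Monte-Carlo error
  expect_equal(colMeans(a$values), colMeans(c$values), tolerance = 0.05)
})

test_that("fluctuations are finite, positive and grow toward the transition", {
  rng <- default_sweep_4d(FALSE)
  sw <- sweep_stability(params_4d(FALSE), rng$r_A_start, rng$r_A_end,
                        n_steps = 5)
  sds_first <- apply(simulate_series(sw$steps[[1]]$params,
                                     sw$steps[[1]]$state,
                                     duration = 500, seed = 3)$values, 2, sd)
  sds_last <- apply(simulate_series(sw$steps[[5]]$params,
                                    sw$steps[[5]]$state,
                                    duration = 500, seed = 3)$values, 2, sd)
  expect_true(all(is.finite(c(sds_first, sds_last))))
  expect_true(all(sds_first > 0))
  expect_gt(mean(sds_last), mean(sds_first))
})

test_that("zero clipping is inactive under default settings", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  ts <- simulate_series(p, eq, duration = 2000, seed = 5)
  expect_lt(ts$meta$n_clipped / ts$meta$n_steps_total, 0.001)
})

test_that("the Ornstein-Uhlenbeck limit matches its closed forms", {
  # 1-species logistic linearizes to dx = lambda x dt + sigma dW with
  # lambda = -r: lag-1 AC = exp(lambda * Delta), var = sigma^2 / (2|lambda|)
  r <- 0.3; sigma <- 0.02; delta <- 0.1
  p <- logistic_params(r = r, c = 0.3, sigma = sigma)
  ts <- simulate_series(p, c(1, 0), noise_spec(sigma = sigma),
                        duration = 1000, sampling_interval = delta,
                        burn_in = 50, seed = 11)
  x <- ts$values[, 1]
  n <- length(x)
  rho_hat <- lag1_autocorrelation(x)
  rho_true <- exp(-r * delta)
  se_rho <- sqrt((1 - rho_true^2) / n)
  expect_lt(abs(rho_hat - rho_true), 3 * se_rho)

  v_hat <- var(x)
  v_true <- sigma^2 / (2 * r)
  n_eff <- n * (1 - rho_true) / (1 + rho_true)
  se_v <- v_true * sqrt(2 / n_eff)
  expect_lt(abs(v_hat - v_true), 3 * se_v)
})

test_that("measurement noise adds the expected variance and is pure", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  base <- simulate_series(p, eq, noise_spec(sigma = 0), duration = 500,
                          burn_in = 10, seed = 1)  # constant series
  before <- base$values
  noisy <- add_measurement_noise(base, 0.08, seed = 2)
  expect_identical(base$values, before)  # input untouched
  sds <- apply(noisy$values, 2, sd)
  se <- 0.08 / sqrt(2 * (nrow(before) - 1))
  expect_true(all(abs(sds - 0.08) < 3 * se))

  # variance additivity on an independent fluctuating series
  fl <- simulate_series(p, eq, duration = 2000, seed = 3)
  fln <- add_measurement_noise(fl, 0.08, seed = 4)
  v0 <- apply(fl$values, 2, var)
  v1 <- apply(fln$values, 2, var)
  expect_equal(v1, v0 + 0.08^2, tolerance = 0.05)

  expect_identical(add_measurement_noise(fl, 0), fl)
})

test_that("length truncation and resolution thinning keep the bookkeeping consistent", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  ts <- simulate_series(p, eq, duration = 100, sampling_interval = 0.1,
                        burn_in = 10, seed = 1)  # 1000 rows
  expect_identical(truncate_length(ts, nrow(ts$values)), ts)
  short <- truncate_length(ts, 100)
  expect_equal(nrow(short$values), 100)
  expect_equal(short$sampling_interval, 0.1)
  expect_error(truncate_length(ts, 5000), class = "ewsbench_parameter_error")

  expect_identical(thin_resolution(ts, 1), ts)
  thin <- thin_resolution(ts, 10)
  expect_equal(nrow(thin$values), 100)
  expect_equal(thin$sampling_interval, 1.0)
  expect_equal(thin$values[2, ], ts$values[11, ])
})

test_that("variable subsetting slices columns and validates indices", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  ts <- simulate_series(p, eq, duration = 50, burn_in = 5, seed = 1)
  expect_identical(select_subset(ts, 1:4)$values, ts$values)
  sub <- select_subset(ts, c(2, 4))
  expect_equal(sub$labels, ts$labels[c(2, 4)])
  expect_equal(ncol(sub$values), 2)
  one <- select_subset(ts, 3)
  expect_equal(ncol(one$values), 1)
  expect_error(select_subset(ts, c(1, 1)), class = "ewsbench_parameter_error")
  expect_error(select_subset(ts, 5), class = "ewsbench_parameter_error")
})

test_that("sweep series are reproducible, step-seeded and constant without noise", {
  rng <- default_sweep_4d(FALSE)
  sw <- sweep_stability(params_4d(FALSE), rng$r_A_start, rng$r_A_end,
                        n_steps = 5)
  a <- generate_sweep_series(sw, length = 100, seed = 9)
  b <- generate_sweep_series(sw, length = 100, seed = 9)
  expect_equal(length(a$series), 5)
  expect_identical(a$series[[3]]$values, b$series[[3]]$values)
  # different steps use different sub-streams
  expect_false(identical(a$series[[1]]$values - sw$steps[[1]]$state[1],
                         a$series[[2]]$values - sw$steps[[2]]$state[1]))

  quiet <- generate_sweep_series(sw, noise_spec(sigma = 0), length = 50,
                                 seed = 9)
  for (s in 1:5)
    expect_lt(max(abs(sweep(quiet$series[[s]]$values, 2,
                            sw$steps[[s]]$state))), 1e-6)
})

test_that("time series roundtrip through delimited text", {
  p <- params_4d(FALSE)
  eq <- as.numeric(find_equilibrium(p))
  ts <- simulate_series(p, eq, duration = 20, burn_in = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mvts(ts, path)
  back <- read_mvts(path)
  expect_equal(back$values, ts$values, tolerance = 1e-8)
  expect_equal(back$sampling_interval, ts$sampling_interval)
  expect_equal(back$labels, ts$labels)
})
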