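test_that("stationary covariance solves the Lyapunov equation", {
  m1 <- ou_model(matrix(0, 3, 3), tau = 1, dt = 0.1, T = 10)
  expect_close(stationary_covariance(m1), diag(3) / 2, tol = 1e-12)

  m2 <- ou_model(matrix(0, 3, 3), tau = 2.5, dt = 0.1, T = 10)
  expect_close(stationary_covariance(m2), diag(3) * 2.5 / 2, tol = 1e-12)

  for (s in 1:5) {
    G <- sample_er_network(20, 0.15, 0.6, seed = s)
    m <- ou_model(G, tau = 0.1, dt = 0.1, T = 10)
    S <- stationary_covariance(m)
    expect_lt(max(abs(m$A %*% S + S %*% t(m$A) + diag(20))), 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("unstable drifts are rejected", {
  G <- diag(2) * 0 + 1.2; diag(G) <- 0   # rho = 1.2
  expect_error(ou_model(G, tau = 0.1, dt = 0.1, T = 10), "not stable")
})

test_that("simulated series match the stationary law", {
  # single-node sanity: lag-1 autocorrelation of an OU process is
  # exp(-dt/tau); with tau = dt this is exp(-1)
  m <- ou_model(matrix(0, 2, 2), tau = 0.1, dt = 0.1, T = 20000)
  ts <- simulate_ou(m, seed = 1)
  x <- ts$values[1, ]
  ac <- cor(x[-1], x[-length(x)])
  expect_lt(abs(ac - exp(-1)), 0.02)

  # multivariate: empirical covariance of a long run converges to the
  # Lyapunov solution
  G <- sample_er_network(10, 0.2, 0.5, seed = 2)
  m <- ou_model(G, tau = 0.1, dt = 0.1, T = 10000)
  ts <- simulate_ou(m, seed = 3)
  S_emp <- tcrossprod(ts$values - rowMeans(ts$values)) / ncol(ts$values)
  S <- stationary_covariance(m)
  expect_lt(norm(S_emp - S, "F") / norm(S, "F"), 0.05)
})

test_that("the exact scheme is marginally stationary across blocks", {
  G <- sample_er_network(5, 0.3, 0.5, seed = 4)
  m <- ou_model(G, tau = 0.1, dt = 0.1, T = 20000)
  ts <- simulate_ou(m, seed = 5)
  blocks <- split(seq_len(ncol(ts$values)),
                  cut(seq_len(ncol(ts$values)), 10))
  vars <- vapply(blocks, function(ix) mean(ts$values[, ix]^2), numeric(1))
  expect_lt(max(abs(vars - mean(vars))) / mean(vars), 0.25)
})

test_that("stationary-noise mode inflates the marginal variance", {
  G <- sample_er_network(5, 0.2, 0.5, seed = 6)
  m <- ou_model(G, tau = 0.1, dt = 0.1, T = 5000)
  v_exact <- mean(simulate_ou(m, seed = 7)$values^2)
  v_lit <- mean(simulate_ou(m, seed = 7, noise = "stationary")$values^2)
  expect_gt(v_lit / v_exact, 1.2)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- ou_model(sample_er_network(6, 0.2, 0.5, seed = 1),
                tau = 0.1, dt = 0.1, T = 50)
  expect_identical(simulate_ou(m, seed = 11)$values,
                   simulate_ou(m, seed = 11)$values)
})

test_that("the hemodynamic kernel has the canonical double-gamma shape", {
  k <- hrf_kernel(0.1)
  expect_equal(k[1], 0)                       # gamma with shape > 1 at 0
  expect_equal(max(k), 1)                     # unit peak
  tpk <- (which.max(k) - 1) * 0.1
  expect_gte(tpk, 5.0); expect_lte(tpk, 6.0)  # mode of the response gamma
  expect_equal(sum(diff(sign(k[k != 0])) != 0), 1)  # one undershoot
})

test_that("HRF filtering is a causal convolution", {
  ts0 <- zlconn_ts(matrix(0, 3, 50), dt = 0.1)
  expect_true(all(apply_hrf(ts0)$values == 0))

  ts1 <- zlconn_ts(matrix(rnorm(100), 2, 50), dt = 0.1)
  ident <- apply_hrf(ts1, kernel = 1)
  expect_equal(ident$values, ts1$values)
  expect_error(apply_hrf(ident), "already applied")

  # white-noise input: output autocovariance equals the kernel
  # autocorrelation (linear filter theory)
  set.seed(8)
  n <- 400000
  k <- hrf_kernel(0.5)
  ts <- zlconn_ts(matrix(rnorm(n), 1, n), dt = 0.5)
  y <- apply_hrf(ts, kernel = k)$values[1, ]
  for (lag in c(0, 3, 10)) {
    theo <- sum(k[1:(length(k) - lag)] * k[(1 + lag):length(k)])
    emp <- mean(y[(1 + lag):n] * y[1:(n - lag)])
    expect_lt(abs(emp - theo) / sum(k^2), 0.05)
  }
})

test_that("observation noise is added at the stated level", {
  ts <- zlconn_ts(matrix(rnorm(2e5), 2, 1e5), dt = 0.1)
  same <- add_observation_noise(ts, 0)
  expect_identical(same$values, ts$values)
  expect_equal(same$snr, Inf)

  noisy <- add_observation_noise(ts, 0.5, seed = 9)
  d <- noisy$values - ts$values
  expect_lt(abs(mean(d^2) - 0.25) / 0.25, 0.02)
  # standardized signal with sigma_obs = 1 has SNR ~ 1
  unit <- add_observation_noise(standardize_ts(ts), 1, seed = 10)
  expect_equal(unit$snr, 1, tolerance = 0.01)
})

test_that("partial observation keeps a consistent node subset", {
  ts <- zlconn_ts(matrix(rnorm(180 * 20), 180, 20), dt = 0.1)
  full <- observe_subset(ts, 1, seed = 1)
  expect_equal(full$nodes, 1:180)
  half <- observe_subset(ts, 0.5, seed = 2)
  expect_equal(nrow(half$ts$values), 90)
  expect_identical(half$ts$values, ts$values[half$nodes, ])
  expect_error(observe_subset(ts, 0), "fraction > 0")
})

test_that("streaming moments equal the composed pipeline", {
  G <- sample_er_network(8, 0.2, 0.5, seed = 12)
  m <- ou_model(G, tau = 0.1, dt = 0.1, T = 300)
  sc <- surrogate_covariance(m, hrf = TRUE, seed = 13)
  set.seed(13)
  ts <- apply_hrf(simulate_ou(m))
  C2 <- sample_covariance(standardize_ts(ts))
  expect_close(sc$C, C2, tol = 1e-12)
  expect_equal(sc$n_samples, m$n_steps)

  # without the filter as well
  sc0 <- surrogate_covariance(m, hrf = FALSE, seed = 14)
  set.seed(14)
  C0 <- sample_covariance(standardize_ts(simulate_ou(m)))
  expect_close(sc0$C, C0, tol = 1e-12)
})
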