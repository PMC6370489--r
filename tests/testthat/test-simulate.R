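test_that("leading_eigenvalue matches trivial and power-iteration oracles", {
  expect_equal(leading_eigenvalue(diag(4)), 1.0)
  expect_equal(leading_eigenvalue(diag(c(3, 1, 2))), 3.0)
  set.seed(2)
  M <- matrix(rnorm(36), 6, 6)
  W <- (M + t(M)) / 2
  v <- rep(1, 6)
  for (i in 1:500) { v <- W %*% v; v <- v / sqrt(sum(v^2)) }
  lam_power <- as.numeric(t(v) %*% W %*% v)
  expect_equal(leading_eigenvalue(W), lam_power, tolerance = 1e-8)
  expect_error(leading_eigenvalue(matrix(1, 2, 3)), "square")
})

test_that("uncoupled noiseless firing rate decays exponentially with tau0", {
  conn <- connectome(matrix(0, 2, 2))
  cfg <- fr_cfg(k = 0, dt = 1e-4, duration = 0.020, tau0 = 0.020)
  nt <- simulate_firing_rate(conn, cfg, init = c(1, 1))
  expect_equal(ncol(nt$values), 200L)
  expect_equal(nt$values[1, 200], exp(-1), tolerance = 0.01)
  # zero initial state is a fixed point
  nt0 <- simulate_firing_rate(conn, cfg, init = c(0, 0))
  expect_true(all(nt0$values == 0))
})

test_that("coupled two-node firing rate decays at the rate of the slow eigenmode", {
  conn <- two_node_conn(0.5)
  k <- 0.4
  cfg <- fr_cfg(k = k, dt = 1e-5, duration = 0.1, tau0 = 0.020)
  nt <- simulate_firing_rate(conn, cfg, init = c(1, 1))
  # matrix-exponential oracle: dx/dt = A x with A = (-I + (k/c1) C)/tau0;
  # c1 = 0.5 so (k/c1) C has eigenvalue k on the symmetric mode
  lam <- (-1 + k) / 0.020
  t_end <- 0.1
  expect_equal(nt$values[1, ncol(nt$values)], exp(lam * t_end),
               tolerance = 0.01)
})

test_that("free Kuramoto rotation returns to its phase after one cycle", {
  conn <- connectome(matrix(0, 2, 2))
  cfg <- km_cfg(k = 0, dt = 1e-4, duration = 1)
  nt <- simulate_kuramoto(conn, cfg, init = c(0, 0), freqs_hz = c(1, 1))
  th_end <- nt$phases[1, ncol(nt$phases)]
  expect_lt(min(abs(c(th_end, th_end - 2 * pi))), 1e-3)
})

test_that("two identical oscillators synchronize at the linearized rate", {
  c <- 0.5
  conn <- two_node_conn(c)
  k <- 2
  phi0 <- 0.1
  cfg <- km_cfg(k = k, dt = 1e-5, duration = 0.4)
  nt <- simulate_kuramoto(conn, cfg, init = c(0, phi0), freqs_hz = c(10, 10))
  phi <- (nt$phases[2, ] - nt$phases[1, ] + pi) %% (2 * pi) - pi
  # small-angle: dphi/dt = -2 k c phi
  t_half <- log(2) / (2 * k * c)
  idx <- round(t_half / cfg$dt)
  expect_equal(phi[idx], phi0 / 2, tolerance = 0.05)
  # dense-dt oracle for the full nonlinear two-oscillator reduction
  dts <- 1e-6
  p <- phi0
  for (i in seq_len(round(t_half / dts))) p <- p + dts * (-2 * k * c * sin(p))
  expect_equal(phi[idx], p, tolerance = 0.01)
})

test_that("strong symmetric coupling drives full phase synchronization", {
  conn <- two_node_conn(0.5)
  cfg <- km_cfg(k = 50, dt = 1e-4, duration = 2)
  nt <- simulate_kuramoto(conn, cfg, init = c(0, 2), freqs_hz = c(10, 10))
  z_end <- mean(exp(1i * nt$phases[, ncol(nt$phases)]))
  expect_gt(abs(z_end), 1 - 1e-3)
})

test_that("halving dt changes deterministic end states by under 1 percent", {
  conn <- tiny_conn(6L, seed = 2L)
  # quantize delays so both step sizes resolve them exactly and the check
  # isolates Euler discretization error
  conn$delays <- round(conn$delays / 2e-3) * 2e-3
  set.seed(9)
  init_r <- runif(6)
  init_p <- runif(6, 0, 2 * pi)
  ends_fr <- lapply(c(1e-3, 5e-4), function(dt) {
    nt <- simulate_firing_rate(conn, fr_cfg(dt = dt, duration = 1, k = 0.9),
                               init = init_r)
    nt$values[, ncol(nt$values)]
  })
  rel <- sqrt(sum((ends_fr[[1]] - ends_fr[[2]])^2)) /
    sqrt(sum(ends_fr[[2]]^2))
  expect_lt(rel, 0.01)
  ends_km <- lapply(c(1e-4, 5e-5), function(dt) {
    nt <- simulate_kuramoto(conn, km_cfg(dt = dt, duration = 1, k = 2),
                            init = init_p, freqs_hz = rep(10, 6))
    nt$values[, ncol(nt$values)]
  })
  relk <- sqrt(sum((ends_km[[1]] - ends_km[[2]])^2)) /
    sqrt(sum(ends_km[[2]]^2))
  expect_lt(relk, 0.01)
})

test_that("subcritical noiseless firing rate decays to zero from random states", {
  conn <- tiny_conn(8L, seed = 4L)
  cfg <- fr_cfg(k = 0.8, dt = 1e-4, duration = 1.5)
  set.seed(2)
  nt <- simulate_firing_rate(conn, cfg, init = runif(8))
  expect_lt(max(abs(nt$values[, ncol(nt$values)])), 1e-3)
})

test_that("Kuramoto phase coherence rises across the low/default/high presets", {
  conn <- generate_synthetic_connectome(66L, seed = 1L)
  coh <- sapply(c(3, 13, 60), function(k) {
    mean(sapply(1:5, function(s) {
      cfg <- simulation_config("kuramoto", k = k, dt = 5e-4, duration = 25,
                               discard = 5, seed = s)
      nt <- simulate_kuramoto(conn, cfg)
      mean(abs(colMeans(exp(1i * nt$phases))))
    }))
  })
  expect_true(coh[1] <= coh[2] && coh[2] <= coh[3])
})

test_that("fixed seeds give bit-identical trajectories", {
  conn <- tiny_conn(6L, seed = 3L)
  cfg <- simulation_config("firing_rate", dt = 1e-3, duration = 2,
                           discard = 0.5, sigma = 2, seed = 11L)
  expect_identical(simulate_firing_rate(conn, cfg)$values,
                   simulate_firing_rate(conn, cfg)$values)
  cfgk <- simulation_config("kuramoto", dt = 1e-3, duration = 2,
                            discard = 0.5, sigma = 2, seed = 11L)
  expect_identical(simulate_kuramoto(conn, cfgk)$phases,
                   simulate_kuramoto(conn, cfgk)$phases)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config("firing_rate", dt = 0), "dt")
  expect_error(simulation_config("firing_rate", duration = 10, discard = 10),
               "discard")
  expect_error(simulation_config("firing_rate", tau0 = 0), "tau0")
  expect_error(simulation_config("firing_rate", sigma = -1), "sigma")
  conn <- tiny_conn(6L)
  expect_error(simulate_firing_rate(conn, km_cfg()), "firing_rate")
  expect_error(simulate_kuramoto(conn, fr_cfg()), "kuramoto")
})
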