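test_that("resting input leaves the hemodynamic system at its fixed point", {
  x <- matrix(0, 3, 600)
  out <- balloon_windkessel(x, dt = 0.1)
  expect_lt(max(abs(out)), 1e-9)
})

test_that("a 1 s box input produces an HRF-like peak matching a dense-dt reference", {
  dt <- 0.01
  T <- round(30 / dt)
  x <- matrix(0, 1, T)
  x[1, seq_len(round(1 / dt))] <- 1
  y <- balloon_windkessel(x, dt = dt)[1, ]
  peak_t <- which.max(y) * dt
  expect_gte(peak_t, 3)
  expect_lte(peak_t, 8)
  # undershoot after the peak
  expect_lt(min(y[(which.max(y) + 1):T]), 0)
  # quarter-dt reference integration
  dt4 <- dt / 4
  x4 <- matrix(0, 1, T * 4)
  x4[1, seq_len(round(1 / dt4))] <- 1
  y4 <- balloon_windkessel(x4, dt = dt4)[1, ]
  expect_lt(abs(which.max(y4) * dt4 - peak_t), 0.1)
})

test_that("balloon treats ROIs independently and commutes with permutation", {
  set.seed(8)
  x <- matrix(rnorm(4 * 500, sd = 0.2), 4, 500)
  x2 <- rbind(x[1, ], x[1, ], x[3, ], x[4, ])
  out <- balloon_windkessel(x2, dt = 0.01)
  expect_identical(out[1, ], out[2, ])
  perm <- c(3, 1, 4, 2)
  expect_identical(balloon_windkessel(x[perm, ], dt = 0.01),
                   balloon_windkessel(x, dt = 0.01)[perm, ])
})

test_that("balloon reports inflow collapse instead of continuing silently", {
  x <- matrix(-5, 1, 5000)
  expect_error(balloon_windkessel(x, dt = 0.01), "inflow")
})

test_that("downsampling keeps constants, lengths, and analytic sines", {
  x <- matrix(2.5, 3, 1000)
  out <- downsample_to_tr(x, dt = 0.01, tr = 0.72)
  expect_equal(ncol(out$values), floor(1000 * 0.01 / 0.72))
  expect_equal(max(abs(out$values - 2.5)), 0, tolerance = 1e-8)

  # 0.1 Hz sine at dt = 0.1 s: compare against the analytic value at the
  # retained sample times (every round(0.72/0.1) = 7th sample)
  dt <- 0.1
  tt <- (0:9999) * dt
  x <- matrix(sin(2 * pi * 0.1 * tt), 1)
  out <- downsample_to_tr(x, dt = dt, tr = 0.72)
  m <- round(0.72 / dt)
  times <- (seq_len(ncol(out$values)) - 1L) * m * dt
  interior <- 20:(ncol(out$values) - 20)
  expect_lt(max(abs(out$values[1, interior] - sin(2 * pi * 0.1 * times[interior]))),
            1e-6)

  # 900 s at the scanner TR gives 1250 samples
  x <- matrix(rnorm(90000), 1)
  expect_equal(ncol(downsample_to_tr(x, dt = 0.01, tr = 0.72)$values),
               floor(900 / 0.72))
  expect_error(downsample_to_tr(x, dt = 0.01, tr = 0.005), "tr")
})

test_that("fused simulate_bold equals the composed module pipeline", {
  conn <- tiny_conn(6L, seed = 2L)
  cfg <- simulation_config("firing_rate", dt = 1e-3, duration = 10,
                           discard = 1, sigma = 2, seed = 4L)
  fused <- simulate_bold(conn, cfg, gain = 0.1, rec_dt = cfg$dt,
                         bold_discard_s = 0)
  nt <- simulate_firing_rate(conn, cfg)
  y <- balloon_windkessel(nt, gain = 0.1)
  composed <- downsample_to_tr(y, dt = cfg$dt, tr = 0.72)
  expect_equal(fused$values, composed$values, tolerance = 1e-12)
})

test_that("simulated BOLD spectra fall with frequency in the analysis band", {
  conn <- generate_synthetic_connectome(66L, seed = 1L)
  for (model in c("firing_rate", "kuramoto")) {
    for (s in 1:2) {
      cfg <- simulation_config(model, dt = 1e-3, duration = 160,
                               discard = 10, seed = s)
      b <- simulate_bold(conn, cfg, bold_discard_s = 10)
      expect_gt(spectral_slope(b), 0)
    }
  }
})
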