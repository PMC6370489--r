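test_that("z-scoring uses the population-SD convention and is idempotent", {
  out <- zscore_series(matrix(c(1, 2, 3), 1))
  expect_equal(out[1, ], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(abs(out[1, 2]), 0)
  again <- zscore_series(out)
  expect_lt(max(abs(again - out)), 1e-12)
  x <- noise_bold(4, 100, seed = 2)
  z <- zscore_series(x)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-10)
  x[2, ] <- 7
  expect_error(zscore_series(x), "ROI 2")
})

test_that("band-pass keeps in-band tones and suppresses out-of-band tones", {
  tr <- 0.72
  tt <- (0:2047) * tr
  probe <- function(f) {
    x <- matrix(sin(2 * pi * f * tt), 1)
    y <- bandpass_filter(x, tr)
    interior <- 200:1800
    sd(y[1, interior]) / sd(x[1, interior])
  }
  expect_gte(probe(0.1), 0.95)
  expect_lte(probe(0.4), 0.10)
  zero <- bandpass_filter(matrix(0, 2, 500), tr)
  expect_equal(max(abs(zero)), 0)
  expect_error(bandpass_filter(matrix(rnorm(500), 1), tr,
                               preprocess_config(band_hi = 0.8)), "Nyquist")
})

test_that("global signal regression removes the across-ROI mean by least squares", {
  x <- matrix(rep(rnorm(50), each = 4), 4)
  out <- global_signal_regression(x)
  expect_lt(max(abs(out)), 1e-10)

  set.seed(6)
  x <- noise_bold(5, 120, seed = 6)
  out <- global_signal_regression(x)
  g <- colMeans(x)
  # normal-equations oracle per row
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X) %*% t(X) %*% t(x)
  expect_equal(out, x - t(X %*% beta), tolerance = 1e-12)
  expect_lt(max(abs(apply(out, 1, function(r) cor(r, g)))), 1e-10)
  expect_error(global_signal_regression(matrix(rnorm(10), 1)), "2 ROIs")
})

test_that("pipeline applies the four steps in the stated order and records flags", {
  x <- noise_bold(6, 400, seed = 9)
  out <- preprocess_pipeline(x, tr = 0.72)
  expect_s3_class(out, "bold_time_series")
  expect_identical(out$flags, c("zscore", "bandpass", "gsr", "zscore"))
  expect_lt(max(abs(rowMeans(out$values))), 1e-10)
  expect_lt(max(abs(sqrt(rowMeans(out$values^2)) - 1)), 1e-10)

  # order matters: GSR before the filter is a different pipeline
  alt <- zscore_series(x)
  alt <- global_signal_regression(alt)
  alt <- bandpass_filter(alt, 0.72)
  alt <- zscore_series(alt)
  expect_gt(max(abs(alt - out$values)), 0)

  # and the pipeline is not idempotent (filtering twice differs)
  twice <- preprocess_pipeline(out)
  expect_gt(max(abs(twice$values - out$values)), 1e-8)
})

test_that("pipeline commutes with ROI permutation and shares one code path", {
  x <- noise_bold(6, 300, seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- preprocess_pipeline(x[perm, ], tr = 0.72)$values
  b <- preprocess_pipeline(x, tr = 0.72)$values[perm, ]
  expect_equal(a, b, tolerance = 1e-10)

  # simulated and surrogate inputs carry the same flag sequence
  surr <- generate_surrogate_rest(surrogate_rest_config(n_rois = 8,
                                                        n_trs = 300, seed = 2))
  f1 <- preprocess_pipeline(surr)$flags
  conn <- tiny_conn(6L)
  sim <- simulate_bold(conn, simulation_config("firing_rate", dt = 1e-3,
                                               duration = 40, discard = 2,
                                               seed = 3),
                       bold_discard_s = 5)
  f2 <- preprocess_pipeline(sim)$flags
  expect_identical(tail(f1, 4), tail(f2, 4))
})
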