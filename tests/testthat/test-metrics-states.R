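test_that("sliding-window FC stacks have the right shape and values", {
  x <- noise_bold(4, 70, seed = 3)
  st <- sliding_window_fc(x, window_trs = 60L)
  expect_equal(nrow(st$windows), 11L)
  expect_equal(ncol(st$windows), 6L)
  # first row equals the Fisher-transformed full-formula correlation on TRs 1-60
  cc <- cor(t(x[, 1:60]))
  expect_equal(st$windows[1, ],
               atanh(pmin(pmax(cc[upper.tri(cc)], -(1 - 1e-6)), 1 - 1e-6)),
               tolerance = 1e-12)
  # perfectly correlated pair clips at atanh(1 - 1e-6)
  y <- noise_bold(2, 70, seed = 4)
  y[2, ] <- y[1, ]
  st2 <- sliding_window_fc(y, window_trs = 60L)
  expect_true(all(st2$windows == atanh(1 - 1e-6)))
  y[2, ] <- 5
  expect_error(sliding_window_fc(y, window_trs = 60L), "window")
  expect_error(sliding_window_fc(noise_bold(3, 50), window_trs = 60L), "T >")
})

test_that("L1 k-means recovers planted clusters and obeys invariants", {
  set.seed(20)
  blob <- function(center, m) sweep(matrix(rnorm(m * 8, sd = 0.2), m, 8), 2,
                                    center, `+`)
  X <- rbind(blob(rep(0, 8), 50), blob(rep(4, 8), 50), blob(rep(-4, 8), 50))
  truth <- rep(1:3, each = 50)
  m <- cluster_states(X, k = 3, replicates = 10, seed = 2)
  # perfect agreement up to label permutation
  tab <- table(m$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 150)
  # inertia equals the summed L1 distances to assigned centroids
  d <- sapply(seq_len(nrow(X)), function(i)
    sum(abs(X[i, ] - m$centroids[m$labels[i], ])))
  expect_equal(m$inertia, sum(d), tolerance = 1e-10)

  # k = 1 gives the componentwise median
  m1 <- cluster_states(X, k = 1, replicates = 3, seed = 2)
  expect_equal(as.vector(m1$centroids), apply(X, 2, median))

  # duplicating all rows leaves the centroids unchanged
  m2 <- cluster_states(rbind(X, X), k = 3, replicates = 10, seed = 2)
  o1 <- m$centroids[order(m$centroids[, 1]), ]
  o2 <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-9)

  expect_error(cluster_states(X[1:2, ], k = 3), "exceeds")
  expect_identical(cluster_states(X, k = 3, replicates = 5, seed = 9)$labels,
                   cluster_states(X, k = 3, replicates = 5, seed = 9)$labels)
})

test_that("per-run state statistics match hand-counted values", {
  model <- structure(list(centroids = rbind(c(1, 0), c(3, 0), c(0, 2)),
                          labels = c(1L, 1L, 1L, 2L, 2L),
                          k = 3L, distance = "manhattan", inertia = 0,
                          run_id = rep("r1", 5)),
                     class = "state_model")
  st <- per_run_state_stats(model, tr = 0.72)
  expect_equal(st$n_states, 2L)
  expect_equal(st$mean_dwell_s, 2.5 * 0.72)
  expect_equal(st$mean_centroid_dist, 2.0) # centroids e1 and 3 e1
  model$labels <- rep(2L, 5)
  st1 <- per_run_state_stats(model, tr = 0.72)
  expect_true(is.na(st1$mean_centroid_dist))
})

test_that("transition analysis matches hand enumeration", {
  model <- structure(list(centroids = matrix(0, 3, 2),
                          labels = c(1L, 2L, 2L, 3L, 1L, 1L),
                          k = 3L, distance = "manhattan", inertia = 0,
                          run_id = rep("r1", 6)),
                     class = "state_model")
  tr <- transition_analysis(model)
  expect_equal(tr$transition_matrix[1, 2], 1 / 3)
  expect_equal(tr$transition_matrix[2, 3], 1 / 3)
  expect_equal(tr$transition_matrix[3, 1], 1 / 3)
  expect_equal(sum(tr$transition_matrix), 1)
  expect_equal(diag(tr$transition_matrix), rep(0, 3))
  expect_equal(tr$sparsity_fraction, 3 / 6)
  model$labels <- rep(1L, 6)
  tr0 <- transition_analysis(model)
  expect_true(tr0$no_transitions)
  expect_equal(sum(tr0$transition_matrix), 0)
  expect_equal(tr0$sparsity_fraction, 0)
})

test_that("surrogate regime switches are detected by the states pipeline", {
  # k planted covariance regimes yield at least k-1 label transitions
  for (s in 1:5) {
    k_true <- 2L + (s %% 3L)
    cfg <- surrogate_rest_config(n_rois = 20, n_trs = 1200, n_states = k_true,
                                 motif_amplitude = 0, seed = 100 + s)
    x <- preprocess_pipeline(generate_surrogate_rest(cfg))
    st <- sliding_window_fc(x, window_trs = 60L)
    model <- cluster_states(st, k = k_true, replicates = 5, seed = s)
    changes <- sum(diff(model$labels) != 0)
    expect_gte(changes, k_true - 1L)
  }
})

test_that("state counts are stable across k = 7, 8, 9 on a 3-state surrogate", {
  stacks <- lapply(1:3, function(s) {
    cfg <- surrogate_rest_config(n_rois = 16, n_trs = 600, n_states = 3,
                                 motif_amplitude = 0, seed = 200 + s)
    sliding_window_fc(preprocess_pipeline(generate_surrogate_rest(cfg)),
                      run_id = paste0("run", s))
  })
  pooled <- pool_fc_stacks(stacks)
  counts <- sapply(c(7, 8, 9), function(k) {
    m <- cluster_states(pooled, k = k, replicates = 5, seed = 1)
    mean(per_run_state_stats(m)$n_states)
  })
  expect_lte(max(counts) - min(counts), 1)
})

test_that("sliding-window FC stationarity: one regime varies less than three", {
  fcdist <- function(n_states) {
    cfg <- surrogate_rest_config(n_rois = 12, n_trs = 500,
                                 n_states = n_states, motif_amplitude = 0,
                                 seed = 77)
    st <- sliding_window_fc(generate_surrogate_rest(cfg))
    W <- st$windows[seq(1, nrow(st$windows), by = 20), ]
    mean(dist(W))
  }
  expect_lt(fcdist(1L), fcdist(3L))
})
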