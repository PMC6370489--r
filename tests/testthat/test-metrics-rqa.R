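test_that("recurrence plots match trivial patterns and a brute-force oracle", {
  x <- matrix(rep(rnorm(5), 8), 5, 8)
  rp <- recurrence_plot(x)
  expect_true(all(rp$R == 1))

  # two alternating orthogonal patterns give a checkerboard
  set.seed(4)
  a <- rnorm(6); b <- rnorm(6)
  b <- b - a * sum(a * b) / sum(a^2) # orthogonalize (in covariance sense)
  a <- a - mean(a); b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a^2)
  x <- sapply(1:10, function(t) if (t %% 2) a else b)
  rp <- recurrence_plot(x, threshold = 0.3)
  expect_equal(rp$R, outer(1:10, 1:10,
                           function(i, j) ((i - j) %% 2 == 0) * 1L),
               ignore_attr = TRUE)

  y <- noise_bold(5, 20, seed = 13)
  rp <- recurrence_plot(y, threshold = 0.3)
  for (i in 1:20) for (j in 1:20)
    expect_identical(rp$R[i, j], (cor(y[, i], y[, j]) >= 0.3) * 1L)

  y[, 3] <- 2
  expect_error(recurrence_plot(y), "TR 3")
  expect_error(recurrence_plot(noise_bold(2, 10)), "3 ROIs")
})

test_that("diagonal length distribution equals an exhaustive run scanner", {
  expect_identical(diagonal_length_distribution(diag(5)), integer(0))

  R <- diag(5)
  R[cbind(1:4, 2:5)] <- 1
  R[cbind(2:5, 1:4)] <- 1
  pl <- diagonal_length_distribution(R)
  expect_identical(pl, c(`4` = 1L))

  set.seed(10)
  M <- matrix(rbinom(144, 1, 0.4), 12, 12)
  R <- 1 * ((M + t(M)) > 0)
  pl <- diagonal_length_distribution(R, l_min = 2)
  oracle <- integer(0)
  for (d in 1:11) {
    run <- 0L
    for (i in 1:(12 - d)) {
      if (R[i, i + d] == 1) run <- run + 1L
      if (R[i, i + d] == 0 || i == 12 - d) {
        if (run >= 2L) oracle <- c(oracle, run)
        run <- 0L
      }
    }
  }
  otab <- table(oracle)
  expect_identical(as.integer(pl), as.integer(otab))
  expect_identical(names(pl), names(otab))
})

test_that("RQA metrics reproduce worked values", {
  m <- rqa_metrics(diag(4))
  expect_equal(m$rr, 0.25)
  expect_true(m$empty_pl)
  expect_equal(m$avg_diag_len, 0)
  expect_equal(m$entropy, 0)

  expect_equal(rqa_metrics(matrix(1, 4, 4))$rr, 1.0)

  # P = {length 3: 1, length 2: 1}  =>  L = 2.5, ENTROPY = ln 2
  R <- diag(7)
  R[cbind(1:3, 3:5)] <- 1; R[cbind(3:5, 1:3)] <- 1     # run of 3 on diag d=2
  R[cbind(5:6, 6:7)] <- 1; R[cbind(6:7, 5:6)] <- 1     # run of 2 on diag d=1
  pl <- diagonal_length_distribution(R)
  expect_identical(sort(as.integer(names(pl))), c(2L, 3L))
  m <- rqa_metrics(R)
  expect_equal(m$avg_diag_len, 2.5)
  expect_equal(m$entropy, log(2))
})

test_that("recurrence rate is monotone in threshold (nested level sets)", {
  y <- noise_bold(6, 40, seed = 21)
  rrs <- sapply(c(0.6, 0.3, 0.0, -0.3), function(th)
    rqa_metrics(recurrence_plot(y, threshold = th))$rr)
  expect_true(all(diff(rrs) > 0))
})

test_that("recurrence rate increases with coupling for both models", {
  conn <- generate_synthetic_connectome(66L, seed = 1L)
  rr <- function(model, level) {
    mean(sapply(1:3, function(s) {
      cfg <- simulation_config(model, k = coupling_presets(model, level),
                               dt = 5e-4, duration = 140, discard = 20,
                               seed = 60 + s)
      b <- preprocess_pipeline(simulate_bold(conn, cfg))
      rqa_metrics(recurrence_plot(b))$rr
    }))
  }
  for (model in c("firing_rate", "kuramoto"))
    expect_gt(rr(model, "high"), rr(model, "low"))
})
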