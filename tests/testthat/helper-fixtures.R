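# shared fixtures built in code; kept small so the full suite stays fast

tiny_conn <- function(n = 10L, seed = 7L) generate_synthetic_connectome(n, seed = seed)

# two-node system with explicit symmetric coupling c and zero delays
two_node_conn <- function(c = 0.5) {
  W <- matrix(c(0, c, c, 0), 2, 2)
  connectome(W)
}

# short deterministic firing-rate config
fr_cfg <- function(...) {
  args <- list(...)
  defaults <- list(model = "firing_rate", dt = 1e-3, duration = 2,
                   discard = 0, sigma = 0, seed = 1L)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

km_cfg <- function(...) {
  args <- list(...)
  defaults <- list(model = "kuramoto", dt = 1e-3, duration = 2,
                   discard = 0, sigma = 0, seed = 1L,
                   coupling_norm = "none")
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

# seeded ROI x T noise matrix
noise_bold <- function(n = 5L, T = 200L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n * T), n, T)
}

# 1/f^beta shaped multi-ROI signal via direct FFT amplitude shaping
shaped_noise <- function(n, T, beta, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * T), n, T)
  freqs <- seq_len(T) - 1L
  freqs <- pmin(freqs, T - freqs)
  shape <- c(0, (freqs[-1L] / freqs[2L])^(-beta / 2))
  t(apply(x, 1L, function(r) Re(fft(fft(r) * shape, inverse = TRUE)) / T))
}
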