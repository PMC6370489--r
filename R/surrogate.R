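#' Configuration for the surrogate resting-state generator
#'
#' The surrogate emulates the features of parcellated resting-state fMRI that
#' the analysis methods are sensitive to: switching covariance regimes (for
#' state analysis), an embedded propagating spatiotemporal motif (for
#' quasiperiodic-pattern discovery), and a `(1/f)^n` power spectrum. Defaults
#' mirror a ~15-minute scan at TR 0.72 s with 66 ROIs and an empirical-like
#' spectral exponent of 0.9; the motif is 28 TRs (~20 s) long, replanted every
#' `motif_period` TRs.
#'
#' @param n_rois number of regions
#' @param n_trs number of time points
#' @param tr repetition time, seconds
#' @param n_states number of covariance regimes (>= 1)
#' @param state_dwell_mean mean dwell time per regime, TRs
#' @param motif_length motif duration, TRs (must be < `n_trs`)
#' @param motif_amplitude motif peak amplitude in innovation-SD units
#'   (0 disables the motif)
#' @param motif_period spacing between motif onsets, TRs
#' @param spectral_exponent exponent n of the (1/f)^n amplitude shaping (>= 0)
#' @param seed integer seed
#' @return a `surrogate_rest_config` list
#' @export
surrogate_rest_config <- function(n_rois = 66L, n_trs = 1250L, tr = 0.72,
                                  n_states = 3L, state_dwell_mean = 80,
                                  motif_length = 28L, motif_amplitude = 1,
                                  motif_period = 2L * motif_length,
                                  spectral_exponent = 0.9, seed = 1L) {
  if (n_states < 1L)
    stop_invalid("invalid argument: n_states must be >= 1")
  if (motif_length >= n_trs)
    stop_invalid("invalid argument: motif_length must be < n_trs")
  if (spectral_exponent < 0)
    stop_invalid("invalid argument: spectral_exponent must be >= 0")
  structure(list(n_rois = as.integer(n_rois), n_trs = as.integer(n_trs),
                 tr = tr, n_states = as.integer(n_states),
                 state_dwell_mean = state_dwell_mean,
                 motif_length = as.integer(motif_length),
                 motif_amplitude = motif_amplitude,
                 motif_period = as.integer(motif_period),
                 spectral_exponent = spectral_exponent, seed = as.integer(seed)),
            class = "surrogate_rest_config")
}

#' Generate a surrogate resting-state scan
#'
#' Builds an ROI x TR series from (i) a hidden Markov chain over `n_states`
#' covariance regimes (geometric dwell with the configured mean) driving
#' correlated Gaussian innovations, (ii) identical per-ROI spectral shaping to
#' a `(1/f)^n` amplitude profile, and (iii) a periodically planted traveling
#' motif whose per-ROI activation peaks are staggered in time. Deterministic
#' for a fixed `cfg$seed`.
#'
#' @param cfg a [surrogate_rest_config()]
#' @return a [bold_time_series()] at `cfg$tr` with the regime labels in
#'   attribute `"states"` and motif onsets in attribute `"motif_onsets"`
#' @export
generate_surrogate_rest <- function(cfg) {
  stopifnot(inherits(cfg, "surrogate_rest_config"))
  n <- cfg$n_rois
  T <- cfg$n_trs
  with_seed(cfg$seed, {
    # one low-rank loading set per covariance regime
    loads <- lapply(seq_len(cfg$n_states),
                    function(s) matrix(rnorm(n * 3L), n, 3L))
    # Markov chain with geometric dwell
    p_stay <- max(0, 1 - 1 / cfg$state_dwell_mean)
    states <- integer(T)
    states[1L] <- sample.int(cfg$n_states, 1L)
    for (t in seq_len(T - 1L)) {
      if (cfg$n_states == 1L || runif(1) < p_stay) {
        states[t + 1L] <- states[t]
      } else {
        others <- setdiff(seq_len(cfg$n_states), states[t])
        states[t + 1L] <- others[sample.int(length(others), 1L)]
      }
    }
    x <- matrix(0, n, T)
    z <- matrix(rnorm(3L * T), 3L, T)
    eps <- matrix(rnorm(n * T), n, T)
    for (t in seq_len(T))
      x[, t] <- loads[[states[t]]] %*% z[, t] + eps[, t]
    # (1/f)^n amplitude shaping, identical across ROIs
    if (cfg$spectral_exponent > 0) {
      freqs <- seq_len(T) - 1L
      freqs <- pmin(freqs, T - freqs) # two-sided bin distances to DC
      shape <- c(0, (freqs[-1L] / freqs[2L])^(-cfg$spectral_exponent / 2))
      for (i in seq_len(n))
        x[i, ] <- Re(fft(fft(x[i, ]) * shape, inverse = TRUE)) / T
    }
    x <- t(scale(t(x))) # unit-SD rows so motif amplitude is in SD units
    onsets <- integer(0)
    if (cfg$motif_amplitude != 0) {
      w <- cfg$motif_length
      peak <- round((seq_len(n) - 1L) / max(1L, n - 1L) * (w / 2))
      bump <- function(center, len) {
        tt <- seq_len(len)
        exp(-((tt - center)^2) / (2 * (w / 8)^2))
      }
      onsets <- seq(1L, T - w, by = cfg$motif_period)
      motif <- t(vapply(seq_len(n),
                        function(i) cfg$motif_amplitude * bump(peak[i] + w / 4, w),
                        numeric(w)))
      for (s in onsets)
        x[, s:(s + w - 1L)] <- x[, s:(s + w - 1L)] + motif
    }
    out <- bold_time_series(x, tr = cfg$tr, flags = "surrogate")
    attr(out, "states") <- states
    attr(out, "motif_onsets") <- onsets
    if (cfg$motif_amplitude != 0) attr(out, "motif") <- motif
    out
  })
}
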