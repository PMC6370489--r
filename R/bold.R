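#' Balloon-Windkessel hemodynamic parameters
#'
#' The canonical constant set (Friston et al. lineage): signal decay
#' kappa = 0.65 1/s, feedback gamma = 0.41 1/s, transit time tau = 0.98 s,
#' Grubb exponent alpha = 0.32, resting oxygen extraction E0 = 0.34, resting
#' blood volume fraction V0 = 0.02, and BOLD observation weights k1 = 7 E0,
#' k2 = 2, k3 = 2 E0 - 0.2.
#'
#' @param kappa,gamma,tau,alpha,E0,V0,k1,k2,k3 see description; `alpha` must
#'   lie in (0, 1), all others positive except `k2`, `k3`
#' @return a named `balloon_params` list
#' @export
balloon_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                           alpha = 0.32, E0 = 0.34, V0 = 0.02,
                           k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2) {
  if (alpha <= 0 || alpha >= 1)
    stop_invalid("invalid argument: alpha must be in (0, 1)")
  if (any(c(kappa, gamma, tau, E0, V0, k1) <= 0))
    stop_invalid("invalid argument: kappa, gamma, tau, E0, V0, k1 must be positive")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3),
            class = "balloon_params")
}

#' BOLD time series container
#'
#' @param values ROI x TR numeric matrix
#' @param tr sampling interval, seconds
#' @param flags ordered character vector of applied processing steps
#' @return a `bold_time_series` object
#' @export
bold_time_series <- function(values, tr, flags = character(0)) {
  check_matrix(values, "values")
  if (any(!is.finite(values)))
    stop_invalid("invalid argument: BOLD values must be finite")
  structure(list(values = values, tr = tr, flags = flags),
            class = "bold_time_series")
}

#' @export
print.bold_time_series <- function(x, ...) {
  cat(sprintf("bold_time_series: %d ROIs x %d samples at %g s (%s)\n",
              nrow(x$values), ncol(x$values), x$tr,
              if (length(x$flags)) paste(x$flags, collapse = " > ")
              else "raw"))
  invisible(x)
}

#' Balloon-Windkessel transform of neural activity
#'
#' Integrates, per ROI, the 4-state hemodynamic system (vasodilatory signal s,
#' inflow f, volume v, deoxyhemoglobin q) driven by the neural observable:
#' `ds/dt = x - kappa s - gamma (f - 1)`, `df/dt = s`,
#' `dv/dt = (f - v^(1/alpha)) / tau`,
#' `dq/dt = (f E(f)/E0 - v^(1/alpha) q / v) / tau` with oxygen extraction
#' `E(f) = 1 - (1 - E0)^(1/f)`, observed as
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`. Euler integration at the
#' neural `dt` from the resting state (s = 0, f = v = q = 1); ROIs are
#' independent.
#'
#' @param neural a `neural_time_series` or a bare ROI x step matrix (then
#'   `dt` must be given)
#' @param params a [balloon_params()]
#' @param gain scalar multiplying the neural drive (default 1)
#' @param dt integration step when `neural` is a bare matrix
#' @return ROI x step matrix of BOLD signal at the neural resolution
#' @export
balloon_windkessel <- function(neural, params = balloon_params(), gain = 1,
                               dt = NULL) {
  stopifnot(inherits(params, "balloon_params"))
  if (inherits(neural, "neural_time_series")) {
    x <- neural$values
    dt <- neural$dt
  } else {
    x <- check_matrix(neural, "neural")
    if (is.null(dt)) stop_invalid("invalid argument: dt required for matrix input")
  }
  if (any(!is.finite(x)))
    stop_invalid("invalid argument: neural input must be finite")
  cpp_balloon(x, dt, unlist(params), gain)
}

#' Downsample a dense signal to the scanner TR
#'
#' Applies a zero-phase low-pass guard (4th-order Butterworth at the Nyquist
#' frequency of the TR, forward-backward) and then keeps every
#' `round(tr/dt)`-th sample, truncated to `floor(T dt / tr)` samples.
#'
#' @param signal ROI x step matrix sampled at `dt`
#' @param dt input sampling interval, seconds
#' @param tr output sampling interval, seconds (default 0.72); must be >= `dt`
#' @param flags processing flags carried into the output
#' @return a [bold_time_series()] at `tr`
#' @export
downsample_to_tr <- function(signal, dt, tr = 0.72, flags = character(0)) {
  x <- as_roi_matrix(signal)
  if (tr < dt)
    stop_invalid("invalid argument: tr (%g) must be >= dt (%g)", tr, dt)
  m <- round(tr / dt)
  n_out <- floor(ncol(x) * dt / tr)
  if (n_out < 1L)
    stop_invalid("invalid argument: signal shorter than one TR")
  if (m > 1L) {
    wc <- (0.5 / tr) / (0.5 / dt) # guard cutoff at the TR Nyquist
    bf <- signal::butter(4, wc, type = "low")
    # filter around the row mean: filtfilt zero-pads, so removing the DC
    # level first avoids edge transients on signals with nonzero baseline
    mu <- rowMeans(x)
    x <- t(apply(x - mu, 1L, function(r) signal::filtfilt(bf, r))) + mu
  }
  idx <- 1L + (seq_len(n_out) - 1L) * m
  idx <- idx[idx <= ncol(x)]
  bold_time_series(x[, idx, drop = FALSE], tr = tr,
                   flags = c(flags, "downsample"))
}

#' Simulate BOLD end-to-end (fused neural + hemodynamic integration)
#'
#' Runs the chosen neural-mass model and the Balloon-Windkessel system in a
#' single streaming pass at `cfg$dt`, recording the hemodynamic output at an
#' intermediate resolution `rec_dt` (the hemodynamic states are smooth on that
#' scale), then applies the guarded decimation to the scanner TR. Equivalent
#' to `downsample_to_tr(balloon_windkessel(simulate_*(conn, cfg)))` but
#' without materializing the full-rate trajectory, so 15-minute runs at
#' dt = 0.1 ms fit in memory. Optionally drops the initial hemodynamic
#' transient (`bold_discard_s`) from the TR series.
#'
#' @inheritParams simulate_firing_rate
#' @param params a [balloon_params()]
#' @param gain neural drive gain; the default 0.1 keeps the hemodynamic
#'   system near its resting operating point (inflow stays positive) for
#'   neural fluctuations of order 1 -- correlation- and spectrum-shape-based
#'   metrics are invariant to it in this linear regime
#' @param tr output sampling interval, seconds
#' @param rec_dt intermediate recording resolution, seconds
#' @param bold_discard_s seconds of BOLD dropped from the start of the TR
#'   series to remove the hemodynamic onset transient (default 20)
#' @return a [bold_time_series()] at `tr`
#' @export
simulate_bold <- function(conn, cfg, params = balloon_params(), gain = 0.1,
                          tr = 0.72, rec_dt = 0.01, bold_discard_s = 20) {
  sc <- sim_common(conn, cfg)
  thin <- max(1L, round(rec_dt / cfg$dt))
  bp <- unlist(params)
  res <- with_seed(cfg$seed, {
    if (cfg$model == "firing_rate") {
      init <- runif(conn$n_rois)
      c1 <- if (cfg$k == 0) 1 else leading_eigenvalue(conn$weights)
      cpp_sim_fr(conn$weights, sc$delay_steps, cfg$k, c1, cfg$tau0,
                 cfg$sigma, cfg$dt, sc$total_steps, sc$discard_steps,
                 init, thin, FALSE, TRUE, bp, gain)
    } else {
      freqs_hz <- rnorm(conn$n_rois, cfg$omega_mean_hz, cfg$omega_sd_hz)
      init <- runif(conn$n_rois, 0, 2 * pi)
      cpp_sim_km(kuramoto_coupling(conn, cfg), sc$delay_steps, cfg$k,
                 2 * pi * freqs_hz,
                 cfg$sigma, cfg$dt, sc$total_steps, sc$discard_steps,
                 init, thin, FALSE, TRUE, bp, gain)
    }
  })
  out <- downsample_to_tr(res$bold, dt = cfg$dt * thin, tr = tr,
                          flags = paste0("simulate_", cfg$model))
  if (bold_discard_s > 0) {
    drop <- floor(bold_discard_s / tr)
    if (drop >= ncol(out$values))
      stop_invalid("invalid argument: bold_discard_s leaves no samples")
    out$values <- out$values[, -seq_len(drop), drop = FALSE]
  }
  out
}
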