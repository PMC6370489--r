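#' Average functional connectivity
#'
#' Pairwise Pearson correlation between ROI time series over the full scan.
#'
#' @param bold ROI x T matrix or `bold_time_series` (T >= 3)
#' @return n x n correlation matrix (unit diagonal, symmetric)
#' @export
average_fc <- function(bold) {
  x <- as_roi_matrix(bold)
  if (ncol(x) < 3L)
    stop_invalid("invalid argument: need at least 3 time points")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    stop_invalid("degenerate input: constant time series at ROI %d",
                 which(sds == 0)[1L])
  cor(t(x))
}

#' Similarity between two FC (or FC-like) matrices
#'
#' Pearson correlation of the strictly-upper-triangle entries.
#'
#' @param a,b square matrices of the same size
#' @return scalar correlation
#' @export
fc_similarity <- function(a, b) {
  check_matrix(a, "a"); check_matrix(b, "b")
  if (!all(dim(a) == dim(b)))
    stop_invalid("invalid argument: matrices must have the same size")
  cor(upper_tri_vec(a), upper_tri_vec(b))
}

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram of each row.
#' Segment length defaults to the largest power of two not exceeding a
#' quarter of the series (at least 64 samples).
#'
#' @param x ROI x T matrix
#' @param fs sampling frequency, Hz
#' @param seg_len segment length in samples
#' @return list with `freq` (Hz, excluding DC) and `power` (ROI x frequency)
#' @export
welch_psd <- function(x, fs, seg_len = NULL) {
  x <- as_roi_matrix(x)
  T <- ncol(x)
  if (is.null(seg_len))
    seg_len <- max(64L, 2L^floor(log2(T / 4)))
  if (seg_len > T) seg_len <- 2L^floor(log2(T))
  step <- seg_len %/% 2L
  starts <- seq(1L, T - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  norm <- sum(w^2) * fs
  nf <- seg_len %/% 2L
  pow <- matrix(0, nrow(x), nf)
  for (i in seq_len(nrow(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[i, s:(s + seg_len - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(fft(seg))^2 / norm
      acc <- acc + sp[2L:(nf + 1L)]
    }
    pow[i, ] <- acc / length(starts)
  }
  list(freq = (seq_len(nf)) * fs / seg_len, power = pow)
}

#' Spectral slope of the ROI-averaged power spectrum
#'
#' Welch spectra are computed per ROI, averaged across ROIs, and a straight
#' line is fit to log power vs. log frequency within `band`; the returned
#' value is the exponent n of the `(1/f)^n` description (minus the fitted
#' slope). Intended for unpreprocessed BOLD.
#'
#' @param bold ROI x T matrix or `bold_time_series` (>= 128 samples)
#' @param band two-element frequency band, Hz (default `c(0.01, 0.25)`)
#' @param tr sampling interval, seconds (taken from a `bold_time_series`)
#' @return the exponent n
#' @export
spectral_slope <- function(bold, band = c(0.01, 0.25), tr = NULL) {
  if (inherits(bold, "bold_time_series") && is.null(tr)) tr <- bold$tr
  x <- as_roi_matrix(bold)
  if (is.null(tr)) stop_invalid("invalid argument: tr required for matrix input")
  if (ncol(x) < 128L)
    stop_invalid("invalid argument: need at least 128 samples")
  ps <- welch_psd(x, fs = 1 / tr)
  sel <- ps$freq >= band[1L] & ps$freq <= band[2L]
  if (sum(sel) < 3L)
    stop_invalid("invalid argument: band [%g, %g] Hz not resolvable at this length",
                 band[1L], band[2L])
  mp <- colMeans(ps$power)[sel]
  fit <- lm(log10(mp) ~ log10(ps$freq[sel]))
  -unname(coef(fit)[2L])
}

#' Point-process coactivation matrix
#'
#' An event (upward threshold crossing) at ROI i and time t occurs when
#' `x[i, t] >= threshold` and `x[i, t-1] < threshold` (the first sample counts
#' as a crossing when already above threshold). Entry (i, j) is the fraction
#' of i's crossings for which j also crosses within `max_lag_trs` TRs in
#' either direction. Rows for ROIs with no crossings are reported as `NA`.
#' Intended for z-scored input (thresholds 0 and 1 correspond to the signal
#' mean and one SD).
#'
#' @param bold ROI x T matrix or `bold_time_series`
#' @param threshold crossing threshold in z-units (default 1)
#' @param max_lag_trs coincidence window half-width, TRs (default 3)
#' @return a `coactivation_matrix` object with the raw (row-normalized,
#'   generally asymmetric) matrix in `$values`, its symmetrization
#'   `(M + t(M))/2` in `$sym`, and per-ROI crossing counts
#' @export
coactivation_matrix <- function(bold, threshold = 1.0, max_lag_trs = 3L) {
  x <- as_roi_matrix(bold)
  n <- nrow(x); T <- ncol(x)
  crossing <- cbind(x[, 1L, drop = FALSE] >= threshold,
                    (x[, -1L, drop = FALSE] >= threshold) &
                      (x[, -T, drop = FALSE] < threshold))
  # near[j, t]: does ROI j cross anywhere within +/- max_lag_trs of t
  near <- crossing
  if (max_lag_trs > 0) {
    for (l in seq_len(max_lag_trs)) {
      near[, seq_len(T - l)] <- near[, seq_len(T - l), drop = FALSE] |
        crossing[, (l + 1L):T, drop = FALSE]
      near[, (l + 1L):T] <- near[, (l + 1L):T, drop = FALSE] |
        crossing[, seq_len(T - l), drop = FALSE]
    }
  }
  counts <- rowSums(crossing)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (counts[i] == 0L) next
    ts_i <- which(crossing[i, ])
    M[i, ] <- rowSums(near[, ts_i, drop = FALSE]) / counts[i]
  }
  structure(list(values = M, sym = (M + t(M)) / 2, threshold = threshold,
                 max_lag = as.integer(max_lag_trs),
                 crossings_per_roi = counts),
            class = "coactivation_matrix")
}

#' @export
print.coactivation_matrix <- function(x, ...) {
  cat(sprintf("coactivation_matrix: %d ROIs, threshold %g, +/-%d TRs, %d-%d crossings/ROI\n",
              nrow(x$values), x$threshold, x$max_lag,
              min(x$crossings_per_roi), max(x$crossings_per_roi)))
  invisible(x)
}
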