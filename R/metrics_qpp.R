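# standardized flattened windows of a scan: d x (T - w + 1), unit-variance
# columns; used by the sliding template correlation
qpp_window_matrix <- function(x, w) {
  n <- nrow(x); T <- ncol(x)
  nw <- T - w + 1L
  V <- matrix(0, n * w, nw)
  for (s in seq_len(nw))
    V[, s] <- as.vector(x[, s:(s + w - 1L)])
  mu <- colMeans(V)
  V <- sweep(V, 2L, mu)
  ss <- sqrt(colSums(V^2))
  list(V = V, ss = ss)
}

# Pearson correlation of a flattened template with every window
qpp_corr_vector <- function(wm, template_vec) {
  tv <- template_vec - mean(template_vec)
  st <- sqrt(sum(tv^2))
  if (st == 0 || any(wm$ss == 0))
    stop_invalid("degenerate input: zero-variance window in QPP correlation")
  as.vector(crossprod(wm$V, tv)) / (st * wm$ss)
}

# local maxima above `thresh` with minimum separation `min_sep`, greedy by
# height
qpp_find_peaks <- function(v, thresh, min_sep) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v >= thresh)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] >= v[cand - 1L] & v[cand] >= v[cand + 1L]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand)
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  sort(keep)
}

#' Quasiperiodic pattern discovery
#'
#' Iterative template-matching: a window-length chunk of the scan seeds a
#' spatiotemporal template; the template's sliding Pearson correlation with
#' the scan is computed; windows at correlation peaks (above a lenient
#' threshold for the first two iterations, a stricter one afterwards, with
#' minimum separation of half a window) are averaged into the next template;
#' iteration stops when successive templates correlate above 0.9999 or after
#' `max_iter` rounds. The procedure is repeated from `n_starts` random seed
#' chunks and the result with the highest sum of peak correlations is
#' returned. A run in which an iteration finds no peaks is returned flagged
#' `converged = FALSE` rather than failing (low-coupling simulations produce
#' unstructured noise-like templates).
#'
#' @param bold ROI x T matrix or `bold_time_series`
#' @param window_s template length, seconds (converted to
#'   `round(window_s / tr)` TRs; 20 s at TR 0.72 gives 28 TRs)
#' @param seed integer seed for the random starting chunks
#' @param tr sampling interval, seconds (taken from a `bold_time_series`)
#' @param peak_thresh_initial,peak_thresh_final correlation thresholds for
#'   peak selection (first two iterations / thereafter)
#' @param max_iter maximum refinement iterations per start
#' @param n_starts number of random starting chunks
#' @return a `qpp_result` with `template` (ROI x window), `corr_vector`,
#'   `peaks`, `n_iterations`, `seed_start`, `converged`
#' @export
find_qpp <- function(bold, window_s = 20, seed = 1L, tr = NULL,
                     peak_thresh_initial = 0.1, peak_thresh_final = 0.2,
                     max_iter = 20L, n_starts = 10L) {
  if (inherits(bold, "bold_time_series") && is.null(tr)) tr <- bold$tr
  x <- as_roi_matrix(bold)
  if (is.null(tr)) stop_invalid("invalid argument: tr required for matrix input")
  w <- round(window_s / tr)
  n <- nrow(x); T <- ncol(x)
  if (T < 4L * w)
    stop_invalid("invalid argument: need at least 4 windows of data (T >= %d)",
                 4L * w)
  if (any(apply(x, 1L, sd) == 0))
    stop_invalid("degenerate input: constant ROI time series")
  nw <- T - w + 1L
  wm <- qpp_window_matrix(x, w)
  min_sep <- floor(w / 2)
  run_from <- function(start) {
    template <- as.vector(x[, start:(start + w - 1L)])
    peaks <- integer(0)
    cv <- NULL
    iters <- 0L
    converged <- FALSE
    repeat {
      iters <- iters + 1L
      cv <- qpp_corr_vector(wm, template)
      thr <- if (iters <= 2L) peak_thresh_initial else peak_thresh_final
      peaks <- qpp_find_peaks(cv, thr, min_sep)
      if (!length(peaks))
        return(list(template = matrix(template, n, w), corr_vector = cv,
                    peaks = peaks, n_iterations = iters, converged = FALSE,
                    score = -Inf))
      newt <- rowMeans(vapply(peaks, function(p)
        as.vector(x[, p:(p + w - 1L)]), numeric(n * w)))
      if (cor(newt, template) > 0.9999) {
        template <- newt
        converged <- TRUE
        break
      }
      template <- newt
      if (iters >= max_iter) break
    }
    cv <- qpp_corr_vector(wm, template)
    peaks <- qpp_find_peaks(cv, peak_thresh_final, min_sep)
    list(template = matrix(template, n, w), corr_vector = cv, peaks = peaks,
         n_iterations = iters, converged = converged,
         score = if (length(peaks)) sum(cv[peaks]) else -Inf)
  }
  with_seed(seed, {
    starts <- sample.int(nw, min(n_starts, nw))
    runs <- lapply(starts, run_from)
    scores <- vapply(runs, `[[`, numeric(1), "score")
    best <- which.max(scores)
    out <- runs[[best]]
    out$seed_start <- starts[best]
    out$window_trs <- w
    out$score <- NULL
    class(out) <- "qpp_result"
    out
  })
}

#' @export
print.qpp_result <- function(x, ...) {
  cat(sprintf("qpp_result: %d ROIs x %d TRs, %d peaks, %d iterations%s\n",
              nrow(x$template), ncol(x$template), length(x$peaks),
              x$n_iterations, if (x$converged) "" else " (unconverged)"))
  invisible(x)
}

#' Align two spatiotemporal templates by circular shift
#'
#' Circularly shifts `b` in time over all window offsets and returns the
#' shift maximizing the Pearson correlation between the flattened templates,
#' ties broken by the smallest non-negative shift.
#'
#' @param a,b ROI x window matrices (or `qpp_result` objects) of equal shape
#' @return list with `shift` (TRs applied to `b`) and `corr` (the maximum)
#' @export
align_templates <- function(a, b) {
  if (inherits(a, "qpp_result")) a <- a$template
  if (inherits(b, "qpp_result")) b <- b$template
  check_matrix(a, "a"); check_matrix(b, "b")
  if (!all(dim(a) == dim(b)))
    stop_invalid("invalid argument: templates must have the same shape")
  w <- ncol(a)
  av <- as.vector(a)
  cors <- vapply(0:(w - 1L), function(s) {
    idx <- ((seq_len(w) - 1L + s) %% w) + 1L
    cor(av, as.vector(b[, idx]))
  }, numeric(1))
  best <- which.max(cors)
  list(shift = best - 1L, corr = cors[best])
}

#' Occurrence statistics of QPP templates across datasets
#'
#' Pools each dataset's sliding-correlation vector into a histogram and
#' compares datasets pairwise with the two-sample Kolmogorov-Smirnov test.
#'
#' @param results named list (>= 2) of `qpp_result` objects or bare
#'   correlation vectors
#' @param breaks histogram break specification (passed to [graphics::hist()]
#'   semantics via [base::cut()]; default 40 equal bins over \[-1, 1\])
#' @return list with `histograms` (per dataset: counts and mids) and `ks`
#'   (data frame of pairwise statistic and p-value)
#' @export
template_occurrence_stats <- function(results, breaks = 40L) {
  if (length(results) < 2L)
    stop_invalid("invalid argument: need at least 2 datasets")
  vecs <- lapply(results, function(r)
    if (inherits(r, "qpp_result")) r$corr_vector else as.numeric(r))
  if (any(vapply(vecs, length, integer(1)) == 0L))
    stop_invalid("invalid argument: empty correlation vector")
  if (is.null(names(vecs)))
    names(vecs) <- paste0("dataset", seq_along(vecs))
  edges <- seq(-1, 1, length.out = breaks + 1L)
  hists <- lapply(vecs, function(v) {
    cnt <- tabulate(cut(v, edges, include.lowest = TRUE), nbins = breaks)
    list(counts = cnt, mids = (edges[-1L] + edges[-length(edges)]) / 2)
  })
  pairs <- utils::combn(names(vecs), 2L)
  ks <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                   statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    kt <- suppressWarnings(ks.test(vecs[[pairs[1L, i]]], vecs[[pairs[2L, i]]]))
    ks$statistic[i] <- unname(kt$statistic)
    ks$p_value[i] <- kt$p.value
  }
  list(histograms = hists, ks = ks)
}
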