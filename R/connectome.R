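#' Synthetic structural connectome
#'
#' Generates a symmetric, non-negative, unit-spectral-norm weight matrix with
#' hemispheric block structure plus a matching fiber-length matrix, standing in
#' for a tractography-derived 66-ROI cortical connectome. ROI centroids are
#' placed on two mirrored rings (one per hemisphere); connection weights are
#' log-normal in magnitude (heavy-tailed, as tractography fiber counts are)
#' and decay exponentially with inter-centroid distance, mimicking
#' tractography's distance bias. Each hemisphere is partitioned into
#' `n_modules` contiguous subnetworks, mirrored across hemispheres;
#' within-module connections are denser and stronger, emulating the
#' community structure of cortical connectomes (the feature that makes
#' functional subnetworks co-activate and de-activate as blocks). Homotopic
#' (mirror-image) pairs are always connected. All interhemispheric weights are
#' scaled by `interhemi_scale` (default 4, compensating tractography's
#' insensitivity to long interhemispheric fibers) before the whole matrix is
#' normalized to unit spectral norm. Fiber lengths are distance-like (centroid
#' distance times a log-normal tortuosity) and rescaled so that the mean
#' conduction delay over connected pairs equals `target_mean_delay` at the
#' given velocity.
#'
#' @param n_rois even number of regions (default 66, split equally L/R)
#' @param seed integer seed; the same seed reproduces the connectome exactly
#' @param velocity mean conduction velocity in m/s (default 5.45)
#' @param interhemi_scale multiplier applied to interhemispheric weights
#'   before normalization (default 4)
#' @param target_mean_delay desired mean delay over connected pairs, seconds
#'   (default 0.011)
#' @param intra_density,inter_density connection probabilities within and
#'   between hemispheres (fixture choices, not empirical claims)
#' @param weight_sdlog SD of the log-normal weight magnitudes; the default 1.5
#'   gives the heavy tail (~3 orders of magnitude) typical of tractography
#'   fiber-count matrices, which is what lets strongly connected pairs
#'   phase-lock before the rest of the network in the Kuramoto model
#' @param n_modules subnetworks per hemisphere (mirrored homotopically)
#' @param module_density,module_boost connection probability and weight
#'   multiplier for same-module pairs (within or across hemispheres)
#' @return an object of class `connectome` with fields `n_rois`, `weights`
#'   (unit spectral norm), `lengths` (mm), `delays` (s), `hemisphere`
#'   ("L"/"R"), `roi_names`, `velocity`
#' @export
generate_synthetic_connectome <- function(n_rois = 66L, seed = 1L,
                                          velocity = 5.45,
                                          interhemi_scale = 4.0,
                                          target_mean_delay = 0.011,
                                          intra_density = 0.35,
                                          inter_density = 0.04,
                                          weight_sdlog = 1.5,
                                          n_modules = 4L,
                                          module_density = 0.9,
                                          module_boost = 3) {
  if (length(n_rois) != 1L || n_rois %% 2L != 0L || n_rois < 4L)
    stop_invalid("invalid argument: n_rois must be even and >= 4 (got %s)",
                 n_rois)
  if (velocity <= 0)
    stop_invalid("invalid argument: velocity must be positive")
  with_seed(seed, {
    nh <- n_rois %/% 2L
    # mirrored ring centroids, mm
    phi <- 2 * pi * (seq_len(nh) - 1L) / nh
    ring <- cbind(55 * cos(phi), 55 * sin(phi))
    coords <- rbind(cbind(-35, ring), cbind(35, ring))
    dmat <- as.matrix(stats::dist(coords))
    hemi <- rep(c("L", "R"), each = nh)
    inter <- outer(hemi, hemi, FUN = "!=")
    module <- rep(ceiling(seq_len(nh) / (nh / n_modules)), 2L)
    same_module <- outer(module, module, FUN = "==")

    W <- matrix(0, n_rois, n_rois)
    L <- matrix(0, n_rois, n_rois)
    for (i in seq_len(n_rois - 1L)) {
      for (j in seq(i + 1L, n_rois)) {
        homotopic <- inter[i, j] && (abs(i - j) == nh)
        p <- if (same_module[i, j]) module_density
             else if (inter[i, j]) inter_density else intra_density
        if (homotopic || runif(1) < p) {
          w <- exp(rnorm(1, 0, weight_sdlog)) * exp(-dmat[i, j] / 60)
          if (same_module[i, j]) w <- w * module_boost
          if (inter[i, j]) w <- w * interhemi_scale
          len <- dmat[i, j] * exp(rnorm(1, log(1.2), 0.15))
          W[i, j] <- W[j, i] <- w
          L[i, j] <- L[j, i] <- len
        }
      }
    }
    W <- normalize_weights(W)
    # calibrate lengths so the mean connected-pair delay hits the target
    con <- W > 0
    diag(con) <- FALSE
    d0 <- delays_from_lengths(L, velocity)
    L <- L * target_mean_delay / mean(d0[con])
    delays <- delays_from_lengths(L, velocity)
    structure(list(n_rois = as.integer(n_rois), weights = W, lengths = L,
                   delays = delays, hemisphere = hemi, modules = module,
                   roi_names = paste0(hemi, sprintf("%02d", c(seq_len(nh),
                                                              seq_len(nh)))),
                   velocity = velocity, seed = seed),
              class = "connectome")
  })
}

#' Build a connectome from explicit matrices
#'
#' Constructor for hand-built systems and for matrices loaded from disk.
#' Delays are derived from `lengths` (mm) and `velocity` (m/s) unless a
#' `delays` matrix (seconds) is given directly.
#'
#' @param weights square non-negative symmetric weight matrix
#' @param lengths fiber lengths, mm (zero where `weights` is zero); default
#'   all-zero (no conduction delays)
#' @param delays optional delay matrix in seconds, overriding `lengths`
#' @param velocity conduction velocity, m/s
#' @param hemisphere,roi_names optional per-ROI labels
#' @param normalize if `TRUE`, rescale `weights` to unit spectral norm
#' @return a `connectome` object
#' @export
connectome <- function(weights, lengths = NULL, delays = NULL,
                       velocity = 5.45, hemisphere = NULL, roi_names = NULL,
                       normalize = FALSE) {
  check_matrix(weights, "weights")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop_invalid("invalid argument: weights must be square")
  if (normalize) weights <- normalize_weights(weights)
  if (is.null(lengths)) lengths <- matrix(0, n, n)
  if (is.null(delays)) delays <- delays_from_lengths(lengths, velocity)
  if (is.null(hemisphere))
    hemisphere <- rep(c("L", "R"), length.out = n)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  structure(list(n_rois = as.integer(n), weights = weights,
                 lengths = lengths, delays = delays, hemisphere = hemisphere,
                 roi_names = roi_names, velocity = velocity),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  con <- x$weights > 0
  diag(con) <- FALSE
  cat(sprintf("connectome: %d ROIs (%d L / %d R), density %.2f\n",
              x$n_rois, sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              mean(con)))
  cat(sprintf("  mean connected-pair delay %.4f ms at %.2f m/s\n",
              1000 * mean(x$delays[con]), x$velocity))
  invisible(x)
}

#' Normalize a weight matrix to unit spectral norm
#'
#' Divides by the largest singular value so that the output has spectral
#' norm 1.
#'
#' @param W square non-negative numeric matrix
#' @return `W / norm(W, "2")`
#' @export
normalize_weights <- function(W) {
  check_matrix(W, "W")
  if (nrow(W) != ncol(W))
    stop_invalid("invalid argument: W must be square")
  if (any(W < 0))
    stop_invalid("invalid argument: W must be non-negative")
  s <- norm(W, type = "2")
  if (s == 0)
    stop_invalid("degenerate input: all-zero weight matrix cannot be normalized")
  W / s
}

#' Conduction delays from fiber lengths
#'
#' @param L fiber-length matrix in mm (non-negative)
#' @param velocity conduction velocity in m/s
#' @return delay matrix in seconds, `L / 1000 / velocity`
#' @export
delays_from_lengths <- function(L, velocity) {
  check_matrix(L, "L")
  if (!is.numeric(velocity) || length(velocity) != 1L || velocity <= 0)
    stop_invalid("invalid argument: velocity must be a positive scalar")
  if (any(L < 0))
    stop_invalid("invalid argument: lengths must be non-negative")
  (L / 1000) / velocity
}

#' Read / write a matrix as TSV
#'
#' Tab-separated values with an optional single header row of ROI names.
#' `read_matrix` detects a header by attempting numeric conversion of the
#' first row and errors (naming the row) on ragged input.
#'
#' @param path file path
#' @return numeric matrix, with `colnames` when a header is present
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop_invalid("parse error: %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stop_invalid("parse error in %s: row %d has %d fields, expected %d",
                 path, which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L])
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  start <- if (has_header) 2L else 1L
  if (has_header && length(lines) == 1L)
    stop_invalid("parse error: %s has a header but no data rows", path)
  vals <- vapply(fields[start:length(fields)],
                 function(f) suppressWarnings(as.numeric(f)),
                 numeric(widths[1L]))
  bad <- which(apply(is.na(vals), 2L, any))
  if (length(bad))
    stop_invalid("parse error in %s: non-numeric value in data row %d",
                 path, bad[1L])
  m <- t(vals)
  dimnames(m) <- NULL
  if (has_header) colnames(m) <- fields[[1L]]
  m
}

#' @rdname read_matrix
#' @param m numeric matrix; column names, when present, are written as a
#'   header row
#' @export
write_matrix <- function(m, path) {
  check_matrix(m, "m")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(m)))
    writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}
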