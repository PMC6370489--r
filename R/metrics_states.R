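#' Sliding-window functional connectivity stack
#'
#' For every window of `window_trs` TRs (advanced by `step`), computes the
#' pairwise Pearson correlation matrix, clips to +/-(1 - 1e-6), applies the
#' Fisher z-transform (atanh), and stores the strictly-upper-triangle entries
#' as one row.
#'
#' @param bold ROI x T matrix or `bold_time_series`
#' @param window_trs window length in TRs (default 60, i.e. 60 x 0.72 s)
#' @param step window advance in TRs (default 1)
#' @param run_id identifier attached to every row (default "run1")
#' @return a `windowed_fc_stack`: `windows` ((T - w)/step + 1 rows x
#'   n(n-1)/2 columns), `window_trs`, `run_id` (per row), `n_rois`
#' @export
sliding_window_fc <- function(bold, window_trs = 60L, step = 1L,
                              run_id = "run1") {
  x <- as_roi_matrix(bold)
  n <- nrow(x); T <- ncol(x)
  if (T <= window_trs)
    stop_invalid("invalid argument: need T > window_trs (T = %d, w = %d)",
                 T, window_trs)
  starts <- seq(1L, T - window_trs + 1L, by = step)
  d <- n * (n - 1L) / 2L
  W <- matrix(0, length(starts), d)
  clip <- 1 - 1e-6
  for (k in seq_along(starts)) {
    s <- starts[k]
    seg <- x[, s:(s + window_trs - 1L), drop = FALSE]
    sds <- apply(seg, 1L, sd)
    if (any(sds == 0))
      stop_invalid("degenerate input: constant ROI in window starting at TR %d", s)
    cc <- cor(t(seg))
    W[k, ] <- atanh(pmin(pmax(upper_tri_vec(cc), -clip), clip))
  }
  structure(list(windows = W, window_trs = as.integer(window_trs),
                 step = as.integer(step),
                 run_id = rep(as.character(run_id), length(starts)),
                 n_rois = n),
            class = "windowed_fc_stack")
}

#' Pool windowed-FC stacks from several runs
#'
#' @param ... `windowed_fc_stack` objects (or a single list of them)
#' @return one `windowed_fc_stack` with rows stacked and `run_id` preserved
#' @export
pool_fc_stacks <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1L && !inherits(stacks[[1L]], "windowed_fc_stack"))
    stacks <- stacks[[1L]]
  stopifnot(all(vapply(stacks, inherits, logical(1), "windowed_fc_stack")))
  out <- stacks[[1L]]
  out$windows <- do.call(rbind, lapply(stacks, `[[`, "windows"))
  out$run_id <- unlist(lapply(stacks, `[[`, "run_id"))
  out
}

#' Cluster windowed FC into discrete brain states
#'
#' k-means with Manhattan (L1) distance for assignment and componentwise
#' median centroid updates (the L1-optimal center). The clustering is run
#' from `replicates` random initializations and the solution minimizing the
#' total within-cluster L1 distance (inertia) is kept. Deterministic for a
#' fixed seed.
#'
#' @param stack a `windowed_fc_stack` (typically pooled over all runs being
#'   compared) or a bare row-matrix of feature vectors
#' @param k number of states (default 7)
#' @param replicates number of random initializations (default 30)
#' @param seed integer seed
#' @param max_iter iteration cap per replicate
#' @return a `state_model` with `centroids` (k x d), `labels` (per window),
#'   `k`, `inertia`, `run_id`
#' @export
cluster_states <- function(stack, k = 7L, replicates = 30L, seed = 1L,
                           max_iter = 100L) {
  X <- if (inherits(stack, "windowed_fc_stack")) stack$windows
       else check_matrix(stack, "stack")
  run_id <- if (inherits(stack, "windowed_fc_stack")) stack$run_id
            else rep("run1", nrow(X))
  m <- nrow(X)
  if (k > m)
    stop_invalid("invalid argument: k (%d) exceeds number of windows (%d)", k, m)
  init <- with_seed(seed, {
    t(vapply(seq_len(replicates), function(i) sample.int(m, k), integer(k)))
  })
  res <- cpp_kmeans_l1(X, as.integer(k), as.integer(max_iter),
                       matrix(as.integer(init), nrow = replicates))
  structure(list(centroids = res$centers, labels = as.integer(res$labels),
                 k = as.integer(k), distance = "manhattan",
                 inertia = res$inertia, run_id = run_id),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d, %d windows, inertia %.1f, occupancy %s\n",
              x$k, length(x$labels), x$inertia,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Per-run state statistics
#'
#' For every run in the stack: the number of unique states visited, the mean
#' dwell time (mean length of consecutive same-label segments, in seconds),
#' and the mean pairwise L2 distance among the centroids of the states that
#' run visits (NA when only one state is visited).
#'
#' @param model a [cluster_states()] result
#' @param tr sampling interval of the underlying BOLD series, seconds
#' @return data frame with columns `run_id`, `n_states`, `mean_dwell_s`,
#'   `mean_centroid_dist`
#' @export
per_run_state_stats <- function(model, tr = 0.72) {
  stopifnot(inherits(model, "state_model"))
  runs <- unique(model$run_id)
  out <- lapply(runs, function(r) {
    lab <- model$labels[model$run_id == r]
    segs <- rle(lab)
    visited <- sort(unique(lab))
    dist <- NA_real_
    if (length(visited) > 1L) {
      cen <- model$centroids[visited, , drop = FALSE]
      dist <- mean(stats::dist(cen))
    }
    data.frame(run_id = r, n_states = length(visited),
               mean_dwell_s = mean(segs$lengths) * tr,
               mean_centroid_dist = dist)
  })
  do.call(rbind, out)
}

#' State transition matrix and sparsity
#'
#' Counts label changes (i to j, i != j) between consecutive windows within
#' each run, pooled across runs, and divides by the total number of changes,
#' so all entries sum to 1 and self-transitions are 0. The sparsity fraction
#' is the number of nonzero off-diagonal cells over k(k-1).
#'
#' @param model a [cluster_states()] result
#' @return list with `transition_matrix` (k x k, zero diagonal) and
#'   `sparsity_fraction`; when no transitions exist the matrix is all zero
#'   and `no_transitions = TRUE` is set
#' @export
transition_analysis <- function(model) {
  stopifnot(inherits(model, "state_model"))
  k <- model$k
  TM <- matrix(0, k, k)
  for (r in unique(model$run_id)) {
    lab <- model$labels[model$run_id == r]
    if (length(lab) < 2L) next
    from <- lab[-length(lab)]
    to <- lab[-1L]
    chg <- from != to
    for (idx in which(chg))
      TM[from[idx], to[idx]] <- TM[from[idx], to[idx]] + 1
  }
  total <- sum(TM)
  if (total == 0)
    return(list(transition_matrix = TM, sparsity_fraction = 0,
                no_transitions = TRUE))
  list(transition_matrix = TM / total,
       sparsity_fraction = sum(TM > 0) / (k * (k - 1L)),
       no_transitions = FALSE)
}
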