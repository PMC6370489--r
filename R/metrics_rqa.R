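#' Recurrence plot of spatial activity patterns
#'
#' R(i, j) = 1 when the Pearson correlation between the ROI activity vectors
#' at TRs i and j is at least `threshold` (0.3 by default). The main diagonal
#' (line of identity) is all ones for any threshold <= 1.
#'
#' @param bold ROI x T matrix or `bold_time_series` (>= 3 ROIs)
#' @param threshold correlation threshold
#' @return a `recurrence_plot` with binary matrix `R` and the threshold
#' @export
recurrence_plot <- function(bold, threshold = 0.3) {
  x <- as_roi_matrix(bold)
  if (nrow(x) < 3L)
    stop_invalid("invalid argument: need at least 3 ROIs")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop_invalid("degenerate input: constant spatial pattern at TR %d",
                 which(sds == 0)[1L])
  cc <- cor(x)
  R <- (cc >= threshold) * 1L
  structure(list(R = R, threshold = threshold, n = ncol(x)),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("recurrence_plot: %d x %d, threshold %g, recurrence rate %.3f\n",
              x$n, x$n, x$threshold, mean(x$R)))
  invisible(x)
}

#' Diagonal line length distribution of a recurrence plot
#'
#' Lengths of maximal runs of ones along diagonals parallel to (and excluding)
#' the main diagonal. By symmetry, each off-diagonal is counted once (upper
#' triangle only). Runs shorter than `l_min` are dropped.
#'
#' @param R a [recurrence_plot()] or binary matrix
#' @param l_min minimum line length (default 2)
#' @return named integer vector: names are lengths l, values the counts P(l);
#'   empty when no qualifying line exists
#' @export
diagonal_length_distribution <- function(R, l_min = 2L) {
  m <- if (inherits(R, "recurrence_plot")) R$R else check_matrix(R, "R")
  N <- nrow(m)
  lens <- integer(0)
  for (d in seq_len(N - 1L)) {
    diag_vals <- m[cbind(seq_len(N - d), seq_len(N - d) + d)]
    r <- rle(diag_vals)
    runs <- r$lengths[r$values == 1]
    lens <- c(lens, runs[runs >= l_min])
  }
  if (!length(lens)) return(integer(0))
  tab <- table(lens)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Recurrence quantification metrics
#'
#' The three line-based statistics of a recurrence plot:
#' recurrence rate `RR = sum(R) / N^2` (over all i, j including the line of
#' identity), average diagonal length `L = sum(l P(l)) / sum(P(l))`, and
#' diagonal-length entropy `ENTROPY = -sum(p(l) ln p(l))` with
#' `p(l) = P(l) / sum(P(l))`, where P(l) is the frequency of diagonal lines of
#' length l >= `l_min` off the main diagonal. When no qualifying diagonal line
#' exists, L and ENTROPY are reported as 0 with `empty_pl = TRUE`.
#'
#' @param R a [recurrence_plot()] or binary matrix
#' @param l_min minimum diagonal line length (default 2)
#' @return an `rqa_metrics` list: `rr`, `avg_diag_len`, `entropy`, `l_min`,
#'   `p_l`, `empty_pl`
#' @export
rqa_metrics <- function(R, l_min = 2L) {
  m <- if (inherits(R, "recurrence_plot")) R$R else check_matrix(R, "R")
  rr <- sum(m) / length(m)
  pl <- diagonal_length_distribution(m, l_min)
  if (!length(pl)) {
    out <- list(rr = rr, avg_diag_len = 0, entropy = 0,
                l_min = as.integer(l_min), p_l = pl, empty_pl = TRUE)
  } else {
    l <- as.numeric(names(pl))
    p <- pl / sum(pl)
    out <- list(rr = rr, avg_diag_len = sum(l * pl) / sum(pl),
                entropy = -sum(p * log(p)), l_min = as.integer(l_min),
                p_l = pl, empty_pl = FALSE)
  }
  class(out) <- "rqa_metrics"
  out
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf("rqa_metrics: RR = %.4f, L = %.2f TRs, ENTROPY = %.3f nats%s\n",
              x$rr, x$avg_diag_len, x$entropy,
              if (x$empty_pl) " (no diagonal lines)" else ""))
  invisible(x)
}
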