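# internal helpers shared across modules

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("invalid argument: %s must be a numeric matrix", name)
  invisible(x)
}

# strictly-upper-triangle vector of a square matrix
upper_tri_vec <- function(m) m[upper.tri(m)]

# pull the ROI x time matrix out of a BoldTimeSeries or accept a bare matrix
as_roi_matrix <- function(x) {
  if (inherits(x, "bold_time_series")) x$values
  else if (inherits(x, "neural_time_series")) x$values
  else check_matrix(x)
}
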