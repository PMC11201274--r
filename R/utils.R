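#' @keywords internal
"_PACKAGE"

## Imports used across the package
#' @importFrom stats median quantile sd var fft mvfft rnorm runif predict
#' @importFrom utils head tail write.table read.table
#' @importFrom Matrix sparseMatrix Diagonal rowSums t
NULL

# Stop with a classed condition so callers/tests can match on error type.
sg_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "seizgraph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

sg_assert <- function(cond, msg, class = "seizgraph_validation_error") {
  if (!isTRUE(cond)) sg_stop(msg, class)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package funnel through this so no global state leaks.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Check that intervals (2-col matrix or list of pairs) are valid within a
# duration: 0 <= start < end <= duration, pairwise non-overlapping.
check_intervals <- function(intervals, duration_s) {
  iv <- as_interval_matrix(intervals)
  if (nrow(iv) == 0L) return(iv)
  sg_assert(all(is.finite(iv)), "seizure intervals must be finite")
  sg_assert(all(iv[, 1] >= 0), "interval start must be >= 0")
  sg_assert(all(iv[, 1] < iv[, 2]), "interval start must precede its end")
  sg_assert(all(iv[, 2] <= duration_s),
            "interval extends beyond recording duration")
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L) {
    sg_assert(all(iv[-1L, 1] >= iv[-nrow(iv), 2]),
              "seizure intervals must not overlap")
  }
  iv
}

as_interval_matrix <- function(intervals) {
  if (is.null(intervals) || length(intervals) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  }
  if (is.list(intervals)) intervals <- do.call(rbind, lapply(intervals, as.numeric))
  iv <- matrix(as.numeric(intervals), ncol = 2L)
  colnames(iv) <- c("start_s", "end_s")
  iv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
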