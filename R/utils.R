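#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded helpers do not disturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current
#' stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-replicate seed table: one integer seed per
# (cell, replicate), derived from the master seed. Any replicate is
# reproducible in isolation given (master_seed, n_cells, n_reps).
replicate_seeds <- function(master_seed, n_cells, n_reps) {
  with_seed(master_seed, {
    matrix(sample.int(.Machine$integer.max - 1L, n_cells * n_reps),
           nrow = n_cells, ncol = n_reps)
  })
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
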