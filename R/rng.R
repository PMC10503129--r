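#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded internals (Monte-Carlo moments, the genetic algorithm, simulators)
#' never perturb the global random stream.
#'
#' @param seed Integer seed. If `NULL`, `expr` is evaluated as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed
#'
#' Deterministically mixes a master seed with one or more integer labels
#' (dataset index, model indicator, stage id) so every stochastic stage has
#' its own named substream. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param ... Integer labels to mix in.
#' @return A positive integer seed.
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (x in unlist(list(...))) {
    h <- (h * 48271 + (as.numeric(x) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
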