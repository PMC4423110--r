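#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded generators never disturb an enclosing
#' simulation. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-stage seed substream
#'
#' Maps a master seed and a stage name to a deterministic 31-bit seed, so
#' one manifest seed drives every random draw in a pipeline run without
#' hidden shared RNG state between stages.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "simulate")
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, length(stage) == 1L, is.character(stage))
  m <- 2147483647          # 2^31 - 1 (Mersenne prime)
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

clip01 <- function(x) {            # dim-preserving clamp to [0, 1]
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mb <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "methblocks_error")))
}
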