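#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so seeded helpers do not disturb the caller's stream.
#' With `seed = NULL` the expression uses the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Spawn a deterministic sub-seed from a master seed
#'
#' Hierarchical seed derivation: each named stage of a pipeline draws its own
#' reproducible stream from one master seed, so stages are independently
#' re-runnable. Result is kept below 2^31.
#'
#' @param seed master integer seed.
#' @param key character tag for the consuming stage.
#' @return An integer seed.
#' @export
spawn_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

#' Central credible interval from draws
#' @param x numeric draws.
#' @param mass interval probability mass.
#' @return length-2 numeric (lower, upper).
#' @keywords internal
central_interval <- function(x, mass) {
  a <- (1 - mass) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}
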