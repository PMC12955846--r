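# shared internal helpers

#' @keywords internal
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a local RNG state.
#'
#' Restores .Random.seed afterwards so callers' RNG streams are not
#' perturbed; if `seed` is NULL the current stream is used (and advanced).
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stable small seed derivation, kept < 2^31
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
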