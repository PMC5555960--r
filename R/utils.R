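`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state, so seeded internals never disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a sub-seed from a global seed and a textual context
#'
#' Every random operation in a pipeline draws its own seed deterministically
#' from the run's global seed, so that re-running any stage in isolation
#' reproduces its output.
#'
#' @param seed Integer global seed.
#' @param context Character tag naming the consumer.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, context) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(context))
  h <- sum(as.integer(charToRaw(context)) * seq_along(charToRaw(context)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Stable hash of an R configuration object
#'
#' MD5 of the object's serialisation; used to stamp artifacts so downstream
#' stages can refuse mismatched inputs.
#'
#' @param x Any serialisable R object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}
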