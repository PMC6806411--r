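# Internal helpers shared across modules.

#' @importFrom stats .lm.fit
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# go through this so a user-level seed fully determines the output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# sprintf("%.17g") representation: doubles survive a write/read round trip.
repr_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
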