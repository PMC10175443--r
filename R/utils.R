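#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards. With `seed = NULL` the code
#' runs against the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with sprintf formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
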