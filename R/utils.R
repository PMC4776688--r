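#' Run an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library functions do not perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from a master seed
#'
#' One master seed fans out to per-subject / per-stage substreams so stages
#' can be re-run in isolation with identical results.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## linear interpolation of interior NA runs, endpoints extended
fill_na_linear <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("cannot interpolate an all-missing series", call. = FALSE)
  if (length(ok) == 1L) return(rep(x[ok], length(x)))
  approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

## circular linear interpolation (for daily profiles that wrap midnight)
fill_na_circular <- function(x) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  y <- fill_na_linear(c(x, x, x))[(n + 1):(2 * n)]
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
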