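#' Derive a child seed from a root seed
#'
#' Deterministic counter-based seed derivation so that every stage of a
#' pipeline (trial generation, weight initialization, training, evaluation)
#' gets an independent, reproducible stream from a single root seed.
#'
#' @param root_seed Integer root seed.
#' @param k Non-negative integer stage counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, k) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.finite(root_seed))
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  root_seed <- abs(as.numeric(root_seed))
  lo <- root_seed %% 100000
  hi <- root_seed %/% 100000
  # all intermediates stay below 2^53 so double arithmetic is exact
  as.integer(((lo * 20011 + k * 7919 + hi * 97) %% 2147483629) + 1)
}

#' Run an expression with a locally-seeded RNG
#'
#' Restores the caller's RNG state afterwards; `seed = NULL` uses the current
#' stream untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_invalid("non-finite values encountered in %s", what)
  }
  invisible(x)
}
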