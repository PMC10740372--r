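# Internal helpers: argument checks and reproducible seed handling.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_cs <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cascadeseg_error"))
}

assert_that <- function(cond, msg, class = "cs_argument_error") {
  if (!isTRUE(cond)) stop_cs(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed.  Stages
#' that need independent randomness draw child seeds from this splitter so
#' that adding phantoms or reordering stages never silently changes the
#' random numbers another stage sees.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to draw.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  assert_that(is_count(seed), "`seed` must be a single integer")
  assert_that(is_count(n) && n >= 1, "`n` must be a positive integer")
  with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
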