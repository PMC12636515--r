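# Internal helpers shared across modules.

#' @useDynLib cardiopatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(class = c("cardiopatch_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_insufficient <- function(...) {
  stop(structure(class = c("cardiopatch_insufficient_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
  if (x < lower || x > upper) {
    stop_invalid(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

odd_at_least <- function(k, minimum = 3L) {
  k <- as.integer(max(k, minimum))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Derive a stream of per-task seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
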