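# Internal helpers: seed management and input checks.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed reproduces an entire benchmark run: each randomised stage
#' (simulation, splits, pool sampling, matching, ...) receives its own seed
#' derived deterministically from the master seed and a stage label, via one
#' step of a Lehmer congruential map modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage stage label (character) or integer offset.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647 # 2^31 - 1, prime
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% m
  } else {
    as.double(stage) %% m
  }
  x <- (abs(as.double(master)) %% m)
  x <- (x * 48271 + off + 1) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(x %% (m - 2) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("'%s' = %g is outside its allowed range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}

# Binary labels used throughout: a named logical vector, TRUE = case.
assert_labels <- function(labels) {
  if (!is.logical(labels) || is.null(names(labels)) || anyNA(labels)) {
    stopf("labels must be a named logical vector (TRUE = case) with no NA")
  }
  if (anyDuplicated(names(labels))) stopf("labels carry duplicated sample ids")
  if (!any(labels)) stopf("no case samples in labels")
  if (!any(!labels)) stopf("no control samples in labels")
  invisible(labels)
}
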