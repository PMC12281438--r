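#' Derive a named random substream seed
#'
#' All stochastic stages derive their own seed from one master seed and a
#' stream name, so the order in which modalities are generated never changes
#' any single modality's draw.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. "bulk", "cells").
#' @param counter Optional non-negative integer for per-draw substreams.
#' @return An integer seed below 2^31.
#' @keywords internal
substreamSeed <- function(seed, stream, counter = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9349 + counter * 65537) %%
               2147483629)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so generators do not
#' disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

#' Round half away from zero
#'
#' Reporting convention for percentages; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @keywords internal
roundHalfUp <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Stops with a uniform message prefix; keeps error text grep-able in tests.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
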