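# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All package errors carry a subclass of `crt80_error` so callers (and the
#' pipeline's exit-code mapping) can distinguish validation problems from
#' computation failures.
#'
#' @param msg message string.
#' @param class error subclass, e.g. `"crt80_validation_error"`.
#' @param ... extra fields attached to the condition.
#' @noRd
crt_stop <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "crt80_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Full-precision number formatting for text output; round-trips doubles.
fmt_num <- function(x) sprintf("%.17g", x)
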