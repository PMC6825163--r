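# Classed conditions so callers (and the CLI) can map failures to exit codes.

abort_aneumech <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message,
                      class = c(class, "aneumech_error"),
                      call = call, ...))
}

#' @noRd
abort_validation <- function(message, ...) {
  abort_aneumech(message, "aneumech_validation_error", call = sys.call(-1), ...)
}

#' @noRd
abort_domain <- function(message, ...) {
  abort_aneumech(message,
                 c("aneumech_domain_error", "aneumech_validation_error"),
                 call = sys.call(-1), ...)
}

#' @noRd
abort_format <- function(message, ...) {
  abort_aneumech(message, c("aneumech_format_error", "aneumech_io_error"),
                 call = sys.call(-1), ...)
}

#' @noRd
abort_parse <- function(message, ...) {
  abort_aneumech(message, c("aneumech_parse_error", "aneumech_io_error"),
                 call = sys.call(-1), ...)
}

#' @noRd
abort_io <- function(message, ...) {
  abort_aneumech(message, "aneumech_io_error", call = sys.call(-1), ...)
}

# scalar checks used throughout the constructors
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_validation(sprintf("`%s` must be %s %g (got %g)",
                             name, if (strict) ">" else ">=", lower, x))
  }
  invisible(x)
}
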