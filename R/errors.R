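# Condition helpers. Every error raised by the package carries class
# "rootsu_error" plus a subclass the CLI maps to an exit code:
#   rootsu_validation_error -> 2, rootsu_io_error -> 3.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rootsu_validation_error", "rootsu_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rootsu_io_error", "rootsu_error")))
}

# Degenerate-input errors (single-level histograms, empty bodies, ...) are a
# flavour of validation error: the input violates a statistical precondition.
stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rootsu_degenerate_error",
                                "rootsu_validation_error", "rootsu_error")))
}

warn_rootsu <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "rootsu_warning"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
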