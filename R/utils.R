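#' @keywords internal
"_PACKAGE"

# Classed condition helper so callers can distinguish validation failures
# (schema, duplication, degenerate denominators, ...) programmatically.
abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mitieval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn <- function(class, msg) {
  warning(structure(
    class = c(class, "mitieval_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# key pasting used throughout for cell identification
cell_key <- function(...) do.call(paste, c(list(...), sep = "\r"))
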