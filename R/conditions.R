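# Classed conditions: every error the package raises carries a specific
# subclass under "odegraph_error" so callers (and the CLI) can dispatch on
# the error family rather than match message text.

stop_odegraph <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "odegraph_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

#' @export
print.odegraph_error <- function(x, ...) {
  cat("<", class(x)[[1]], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}
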