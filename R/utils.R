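# Shared internals: classed conditions so callers can distinguish contract
# violations (bad arguments), inapplicable template lookups, state errors
# (e.g. re-expanding a node), and configuration errors.

stop_egmcts <- function(class, message) {
  stop(structure(
    class = c(paste0("egmcts_", class, "_error"), "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
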