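# Classed conditions so callers can distinguish failure modes programmatically.

rmt_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "rmtnet_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
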