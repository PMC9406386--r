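# condition helpers: all package errors carry class "icg_error" plus a
# specific subclass so callers (and the CLI) can distinguish validation,
# signal-detection, calibration and I/O failures

stop_icg <- function(message, class, data = list()) {
  cnd <- structure(
    class = c(class, "icg_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cnd)
}
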