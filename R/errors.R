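# Typed condition system. Every error raised by the package carries the class
# "emibayes_error" plus a specific subclass so callers (and the CLI exit-code
# mapping) can distinguish validation problems from I/O from model misuse.

emibayes_error_classes <- c(
  "format", "validation", "context", "parameter", "model",
  "inconsistent_evidence", "oracle_scope", "structure", "elicitation",
  "io", "input"
)

abort_emibayes <- function(class, message, ...) {
  class <- match.arg(class, emibayes_error_classes)
  cond <- structure(
    class = c(paste0("emibayes_", class, "_error"), "emibayes_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_emibayes_error <- function(x) inherits(x, "emibayes_error")
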