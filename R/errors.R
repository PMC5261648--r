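# Classed conditions so callers can distinguish failure modes programmatically.
# All conditions inherit from "fg_error" and from the specific class given.
fg_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "fg_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
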