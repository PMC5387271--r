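# Internal condition helpers. All package errors inherit from "kinpipe_error"
# plus a specific subclass so callers can route on failure kind.

kp_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "kinpipe_error")))
}

kp_check <- function(ok, msg, class = "kinpipe_validation_error") {
  if (!isTRUE(ok)) kp_stop(msg, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
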