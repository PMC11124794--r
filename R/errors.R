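# Condition helpers. Error classes let callers (and the CLI) distinguish
# configuration/validation problems (exit 2) from runtime failures (exit 1).

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "poseclass_validation_error", ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = "poseclass_config_error", ...)
}

abort_integrity <- function(message, ...) {
  rlang::abort(message, class = "poseclass_integrity_error", ...)
}

abort_parse <- function(message, ...) {
  rlang::abort(message, class = c(
    "poseclass_parse_error",
    "poseclass_validation_error"
  ), ...)
}

abort_state <- function(message, ...) {
  rlang::abort(message, class = "poseclass_state_error", ...)
}

.assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_validation(paste0(what, " must be finite numbers."))
  }
  invisible(x)
}
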