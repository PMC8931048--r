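# Classed conditions so callers (and the CLI) can map failures to exit codes.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epicmml_validation_error", "epicmml_error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epicmml_parse_error", "epicmml_error")))
}

abort_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epicmml_numeric_error", "epicmml_error")))
}
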