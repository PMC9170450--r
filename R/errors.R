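# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors -> 2, numerical errors -> 3.

stop_validation <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("wetval_validation_error", "error")))
}

stop_numeric <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("wetval_numeric_error", "error")))
}
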