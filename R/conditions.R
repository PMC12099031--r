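# Classed error helpers so callers (and the simulation harness) can
# distinguish recoverable method failures from programming errors.
icc_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "icc_error")))
}

icc_input_error <- function(message) icc_error(message, "icc_input_error")
icc_dimension_error <- function(message) icc_error(message, "icc_dimension_error")
icc_degenerate_error <- function(message) icc_error(message, "icc_degenerate_error")
icc_method_undefined_error <- function(message) icc_error(message, "icc_method_undefined_error")
icc_domain_error <- function(message) icc_error(message, "icc_domain_error")
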