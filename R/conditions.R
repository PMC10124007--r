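# Classed conditions so callers (and the CLI) can distinguish bad invocations
# from bad data. Both inherit "gtcomp_error".

stop_input <- function(msg, ..., class = character()) {
  stop(structure(
    class = c(class, "gtcomp_input_error", "gtcomp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_data <- function(msg, ..., class = character()) {
  stop(structure(
    class = c(class, "gtcomp_data_error", "gtcomp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
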