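# Classed conditions so callers (and the CLI) can distinguish bad input files
# from bad argument values without parsing messages.

rrm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "rrm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) rrm_stop(msg, "rrm_validation_error")
stop_not_found  <- function(msg) rrm_stop(msg, "rrm_not_found_error")
stop_domain     <- function(msg) rrm_stop(msg, "rrm_domain_error")
stop_io         <- function(msg) rrm_stop(msg, "rrm_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
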