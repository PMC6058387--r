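# Classed conditions so callers can distinguish validation failures.
ct_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ctewas_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_format   <- function(msg) ct_abort(msg, "ctewas_format_error")
abort_parse    <- function(msg) ct_abort(msg, "ctewas_parse_error")
abort_contract <- function(msg) ct_abort(msg, "ctewas_contract_error")
abort_config   <- function(msg) ct_abort(msg, "ctewas_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
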