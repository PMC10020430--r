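# Structured error conditions. The CLI maps classes to exit codes:
# input/format/param/consistency -> 2, capability -> 3.

abort_ataxvoice <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ataxvoice_error"), call = call))
}

abort_input <- function(msg) abort_ataxvoice(msg, "ataxvoice_input_error")
abort_format <- function(msg) abort_ataxvoice(msg, "ataxvoice_format_error")
abort_param <- function(msg) abort_ataxvoice(msg, "ataxvoice_param_error")
abort_consistency <- function(msg) abort_ataxvoice(msg, "ataxvoice_consistency_error")
abort_capability <- function(msg) abort_ataxvoice(msg, "ataxvoice_capability_error")
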