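# Typed conditions so callers (and the CLI) can map failures to exit codes.

pv_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pv_error"), call = call))
}

stop_config <- function(msg) pv_stop(msg, "pv_config_error")
stop_schema <- function(msg) pv_stop(msg, "pv_schema_error")
stop_integrity <- function(msg) pv_stop(msg, "pv_integrity_error")
stop_state <- function(msg) pv_stop(msg, "pv_state_error")
stop_domain <- function(msg) pv_stop(msg, "pv_domain_error")
stop_fit <- function(msg) pv_stop(msg, "pv_fit_error")
stop_spec <- function(msg) pv_stop(msg, "pv_spec_error")
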