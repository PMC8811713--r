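# Structured error conditions so callers (and tests) can distinguish
# schema problems from value-level validation, domain errors on parameters,
# and model-configuration errors.

rlddm_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rlddm_error", "error", "condition")))
}

abort_schema <- function(msg) rlddm_abort(msg, "rlddm_schema_error")
abort_validation <- function(msg) rlddm_abort(msg, "rlddm_validation_error")
abort_domain <- function(msg) rlddm_abort(msg, "rlddm_domain_error")
abort_config <- function(msg) rlddm_abort(msg, "rlddm_config_error")
abort_parse <- function(msg) rlddm_abort(msg, "rlddm_parse_error")
abort_precondition <- function(msg) rlddm_abort(msg, "rlddm_precondition_error")
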