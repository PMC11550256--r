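# Structured conditions shared across the package.  Four classes map onto the
# CLI exit codes: input (1), domain (2), guard (3); order errors are a domain
# subclass so callers can test for the violated-pair report specifically.

stop_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("cherrycount_input_error", "cherrycount_error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("cherrycount_domain_error", "cherrycount_error")))
}

stop_order <- function(msg) {
  stop(errorCondition(msg, class = c("cherrycount_order_error",
                                     "cherrycount_domain_error",
                                     "cherrycount_error")))
}

stop_guard <- function(msg) {
  stop(errorCondition(msg, class = c("cherrycount_guard_error", "cherrycount_error")))
}
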