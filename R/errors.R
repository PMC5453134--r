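# Typed conditions so callers (in particular the fitter) can distinguish a
# chain-locking event or a history violation from a genuine programming error.

stop_locking <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("mullins_locking_error", "mullins_error")))
}

stop_history <- function(msg) {
  stop(errorCondition(msg, class = c("mullins_history_error", "mullins_error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("mullins_domain_error", "mullins_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}
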