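# Classed conditions so callers (and the CLI) can distinguish user input
# problems from configuration problems and non-physical fits.

abort_prrt <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "prrtdose_error"), call = call))
}

warn_prrt <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "prrtdose_warning")))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_prrt(sprintf("`%s` must be a single finite number", name),
               "prrtdose_domain_error")
  }
  invisible(x)
}
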