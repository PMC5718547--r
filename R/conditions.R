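# Classed conditions so callers can trap specific failure modes.
c4_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("cine4dqa_", class), "cine4dqa_error")))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    c4_stop(sprintf("'%s' must be a single finite number", name), "invalid_argument")
  invisible(x)
}
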