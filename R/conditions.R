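# Classed error conditions so callers can distinguish failure modes
# programmatically (testthat::expect_error(class = ...), CLI exit handling).

abort_baroloop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("baroloop_", class), "baroloop_error"),
    call = call
  ))
}

stopifnot_scalar_finite <- function(x, name, class = "invalid_argument") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_baroloop(sprintf("`%s` must be a finite numeric scalar", name), class)
  }
  invisible(x)
}
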