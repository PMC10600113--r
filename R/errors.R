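# Classed conditions so callers can distinguish bad measurements from bad
# schemas without string-matching messages.

pj_stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("paleojaw_", class), "paleojaw_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_positive <- function(x, what) {
  if (length(x) == 0L || anyNA(x) || !is.numeric(x) || any(x <= 0)) {
    pj_stop("invalid_measurement",
            sprintf("`%s` must be positive and non-missing", what))
  }
  invisible(x)
}

check_finite <- function(x, what) {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x))) {
    pj_stop("invalid_field", sprintf("`%s` must be finite", what))
  }
  invisible(x)
}
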