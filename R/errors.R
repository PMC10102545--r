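## Condition helpers: every user-facing failure gets a named condition class
## ("ltk_<reason>") so callers and tests can distinguish failure modes.

ltk_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "ltk_error")))
}

ltk_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "ltk_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)))
    ltk_stop("ltk_bad_point", "%s must be 3 finite coordinates", what)
  as.numeric(p)
}
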