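# Structured conditions: every user-facing failure carries a subclass so
# callers (and the CLI) can distinguish usage errors from data errors.

moltk_stop <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  cond <- structure(
    class = c(class, "moltk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}

moltk_warn <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  warning(warningCondition(msg, class = c(class, "moltk_warning")))
}
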