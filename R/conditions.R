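# Structured error conditions. Every user-facing failure signals a condition of
# class c("fastavfs_<what>", "fastavfs_error", "error"), so callers (and the
# vfs layer, which maps some errors onto not-found semantics) can dispatch on
# the failure kind rather than on message text.

fastavfs_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "fastavfs_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_fastavfs_error <- function(x, class = "fastavfs_error") inherits(x, class)
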