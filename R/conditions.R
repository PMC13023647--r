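# Classed conditions so callers (and the CLI) can map failures to exit codes
# without string-matching messages.

abort_fourcv <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("fourcv_", class), "fourcv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @keywords internal
is_fourcv_error <- function(x) inherits(x, "fourcv_error")
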