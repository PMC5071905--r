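#' @keywords internal
#' @noRd
eq_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "echoquant_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
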