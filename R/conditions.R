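# Classed conditions so callers (and the CLI exit-code map) can distinguish
# failure classes without string matching.

pdblake_condition <- function(class, message, ...) {
  structure(
    class = c(class, "pdblake_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_compression <- function(message, file = NA_character_) {
  stop(pdblake_condition("pdblake_compression_error", message, file = file))
}

stop_malformed_line <- function(message, line = NA_integer_, file = NA_character_) {
  stop(pdblake_condition("pdblake_malformed_line_error", message,
                         line = line, file = file))
}

stop_oversize_record <- function(message, file = NA_character_, index = NA_integer_) {
  stop(pdblake_condition("pdblake_oversize_record_error", message,
                         file = file, index = index))
}

stop_trailing_data <- function(message, file = NA_character_) {
  stop(pdblake_condition("pdblake_trailing_data_error", message, file = file))
}

stop_usage <- function(message) {
  stop(pdblake_condition("pdblake_usage_error", message))
}

stop_io <- function(message, file = NA_character_) {
  stop(pdblake_condition("pdblake_io_error", message, file = file))
}
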