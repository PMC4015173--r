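# Structured error conditions.  Every user-facing failure mode gets its own
# condition class so callers (and the CLI) can react without matching on
# message text.

rinchi_error <- function(class, message, ...) {
  structure(
    class = c(class, "rinchi_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_parse <- function(message, line = NA_integer_, ...) {
  stop(rinchi_error("rinchi_parse_error", message, line = line, ...))
}

stop_conversion <- function(message, engine_message = NULL, ...) {
  stop(rinchi_error("rinchi_conversion_error", message,
                    engine_message = engine_message, ...))
}

stop_format <- function(message, index = NA_integer_, ...) {
  stop(rinchi_error("rinchi_format_error", message, index = index, ...))
}

stop_validation <- function(message, rule = NA_character_, ...) {
  stop(rinchi_error("rinchi_validation_error", message, rule = rule, ...))
}
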