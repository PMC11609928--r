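# Classed conditions shared across the package. Every user-facing failure mode
# maps onto one of these so callers (and the CLI) can branch on class rather
# than on message text.

abort_acumap <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "acumap_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_invalid_input <- function(message) abort_acumap(message, "acumap_invalid_input")
abort_degenerate <- function(message) abort_acumap(message, "acumap_degenerate_geometry")
abort_lookup <- function(message) abort_acumap(message, "acumap_lookup_error")
abort_parse <- function(message) abort_acumap(message, "acumap_parse_error")
abort_validation <- function(message) abort_acumap(message, "acumap_validation_error")
abort_rule <- function(message) abort_acumap(message, "acumap_rule_error")

log_msg <- function(level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  threshold <- getOption("acumap.log_level", "warn")
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("%s [%s] acumap: %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), toupper(level),
                    paste0(..., collapse = "")))
  }
  invisible(NULL)
}
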