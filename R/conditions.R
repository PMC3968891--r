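# Condition constructors. Every error the package raises carries the class
# "beadio_error" plus one subclass identifying the failure mode, so callers
# (and the CLI) can branch on error class rather than message text.

beadio_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "beadio_error"), ...)
}

stop_malformed <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_malformed", ...)
}

stop_not_idat <- function(message, offset = 0, ...) {
  beadio_abort(message, class = "beadio_error_not_idat", offset = offset, ...)
}

# `offset` is the 0-based byte position of the first offending byte
stop_corrupt <- function(message, offset, ...) {
  beadio_abort(
    sprintf("%s (at byte offset %s)", message, format(offset, scientific = FALSE)),
    class = "beadio_error_corrupt", offset = offset, ...
  )
}

stop_missing_key <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_missing_key", ...)
}

stop_wrong_key <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_wrong_key", ...)
}

stop_corrupt_field <- function(message, field = NULL, ...) {
  beadio_abort(message, class = "beadio_error_corrupt_field", field = field, ...)
}

stop_dialect <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_dialect", ...)
}

stop_validation <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_validation", ...)
}

stop_manifest <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_malformed_manifest", ...)
}

stop_empty_overlap <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_empty_overlap", ...)
}

stop_usage <- function(message, ...) {
  beadio_abort(message, class = "beadio_error_usage", ...)
}

warn_beadio <- function(message, class) {
  rlang::warn(message, class = c(class, "beadio_warning"))
}
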