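#' @keywords internal
"_PACKAGE"

# Structured conditions: every user-facing failure carries a stable class so
# the CLI can map it to a distinct exit code and tests can assert on it.

nmr_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nmrbridge_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

nmr_warn <- function(message, class = "nmrbridge_warning") {
  warning(structure(
    class = c(class, "nmrbridge_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# One-line structured log records on stderr.  Levels: 0 quiet, 1 normal,
# 2 verbose.  The active level is a package option so the CLI flags map
# straight onto it.
nmr_log <- function(stage, message, level = 1L) {
  if (getOption("nmrbridge.log_level", 1L) >= level) {
    cat(sprintf("[%s] %s\n", stage, message), file = stderr())
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dir <- function(path) file.exists(path) && dir.exists(path)

# Exit codes per error class (CLI contract).
nmr_exit_code <- function(cond) {
  classes <- class(cond)
  codes <- c(
    invalid_accession_error   = 2L,
    io_error                  = 3L,
    unrecognized_format_error = 4L,
    validation_error          = 5L,
    empty_selection_error     = 6L,
    transform_error           = 7L,
    truncated_file_error      = 8L,
    unsupported_dtype_error   = 8L,
    malformed_parameter_error = 8L,
    not_found_error           = 9L,
    transport_error           = 10L,
    usage_error               = 64L
  )
  for (cl in names(codes)) if (cl %in% classes) return(codes[[cl]])
  1L
}
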