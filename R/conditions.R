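# Typed error conditions.  Every error raised by the package carries the
# "taxcat_error" class plus a specific subclass so callers (and the CLI) can
# branch on the failure kind rather than on message text.

taxcat_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "taxcat_error"), ...)
}

abort_format      <- function(message, ...) taxcat_abort(message, "taxcat_format_error", ...)
abort_referential <- function(message, ...) taxcat_abort(message, "taxcat_referential_error", ...)
abort_uniqueness  <- function(message, ...) taxcat_abort(message, "taxcat_uniqueness_error", ...)
abort_parse       <- function(message, ...) taxcat_abort(message, "taxcat_parse_error", ...)
abort_compose     <- function(message, ...) taxcat_abort(message, "taxcat_compose_error", ...)
abort_lookup      <- function(message, ...) taxcat_abort(message, "taxcat_lookup_error", ...)
abort_coverage    <- function(message, ...) taxcat_abort(message, "taxcat_coverage_error", ...)
abort_parameter   <- function(message, ...) taxcat_abort(message, "taxcat_parameter_error", ...)
abort_conflict    <- function(message, ...) taxcat_abort(message, "taxcat_conflict_error", ...)
abort_arity       <- function(message, ...) taxcat_abort(message, "taxcat_arity_error", ...)

# Resolution failures distinguish "never heard of this object id" from
# "object id known, but not under that version token".
abort_unknown_object <- function(message, ...) {
  taxcat_abort(message, c("taxcat_unknown_object_error", "taxcat_resolution_error"), ...)
}
abort_unknown_version <- function(message, ...) {
  taxcat_abort(message, c("taxcat_unknown_version_error", "taxcat_resolution_error"), ...)
}
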