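# Internal error helpers: every user-facing failure carries a condition class
# so callers (and the CLI) can distinguish format, row-level, and usage errors.

abort_format <- function(msg) {
  rlang::abort(msg, class = "operotext_format_error")
}

abort_row <- function(msg, row) {
  rlang::abort(sprintf("%s (row %d)", msg, as.integer(row)),
               class = "operotext_row_error", row = as.integer(row))
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = "operotext_usage_error")
}

abort_annotation <- function(msg) {
  rlang::abort(msg, class = "operotext_annotation_error")
}

#' @importFrom rlang %||%
NULL

# Deterministic, seed-derived sub-seed that stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647L)
}
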