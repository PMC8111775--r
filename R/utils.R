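# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Consistent classed errors so callers can condition on failure modes.
ptj_abort <- function(message, class = "ptj_error", ...) {
  rlang::abort(message, class = c(class, "ptj_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    ptj_abort(sprintf("`%s` must be numeric and non-missing.", name),
              class = "ptj_error_argument")
  }
  if (any(x < lower) || any(x > upper)) {
    ptj_abort(sprintf("`%s` must lie in [%s, %s].", name, lower, upper),
              class = "ptj_error_argument")
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ptj_abort(sprintf("`%s` is missing column(s): %s.", name,
                      paste(missing, collapse = ", ")),
              class = "ptj_error_argument")
  }
  invisible(df)
}

# Derive a reproducible sub-stream seed from a base seed and a fixed offset,
# kept below .Machine$integer.max so set.seed() accepts it.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483587)
}
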