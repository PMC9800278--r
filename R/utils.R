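## internal input checkers ----------------------------------------------------

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) abort(sprintf("`%s` must be finite.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonnegative && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_columns <- function(data, cols, name = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

## seed helper: derive a stream-specific 31-bit seed from a base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
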