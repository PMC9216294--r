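# Internal helpers shared across modules.

# Last observation carried forward over a numeric vector; leading NAs stay NA.
locf <- function(x) {
  idx <- cumsum(!is.na(x))
  out <- x[!is.na(x)][pmax(idx, 1L)]
  out[idx == 0L] <- NA_real_
  out
}

# Percentage of a count over a total, rounded to `digits` decimals.
# Mirrors the usual cohort-table convention (53% = round to integer,
# 15.1% = one decimal).
pct <- function(count, total, digits = 0) {
  if (total == 0) return(NA_real_)
  round(100 * count / total, digits)
}

# A seeded child seed: deterministic derivation of per-task seeds from a
# master seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483647)
}

assert_cols <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s: missing required column(s): %s", where,
              paste(missing, collapse = ", ")),
      class = "ventwatch_schema_error"
    )
  }
  invisible(df)
}

vw_log <- function(stage, msg, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(msg, ...)),
         class = "ventwatch_log")
}
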