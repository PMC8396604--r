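# Internal validation helpers shared across modules.

check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame, not %s.", what, class(df)[1]))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_nonneg <- function(x, name, allow_na = FALSE) {
  if (!allow_na && any(is.na(x))) {
    abort(sprintf("`%s` contains missing values.", name))
  }
  if (any(x < 0, na.rm = TRUE)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

check_count_scalar <- function(x, name, min = 0) {
  if (length(x) != 1 || is.na(x) || x < min || x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, closed = TRUE) {
  bad <- is.na(x) | if (closed) x < 0 | x > 1 else x <= 0 | x >= 1
  if (any(bad)) abort(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

# Tibble subclass tagging so results carry their type for autoplot()/tidy().
new_result <- function(df, class) {
  structure(df, class = c(class, class(tibble())))
}
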