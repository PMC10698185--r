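# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stop with a consistent message when `cond` is FALSE.
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Positive integer scalar check for counts.
check_count <- function(x, name) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x >= 1 && x == floor(x),
             "`", name, "` must be a positive integer, got ", deparse(x))
  as.integer(x)
}

# Required columns check for loaded/passed tables.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  check_that(length(missing) == 0,
             what, " is missing required column(s): ",
             paste(missing, collapse = ", "))
  invisible(df)
}
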