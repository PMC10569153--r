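# internal helpers shared across modules

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream index.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
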