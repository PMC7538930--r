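# Internal helpers shared across modules.

# Case-insensitive gene-symbol key: human symbols are uppercase, mouse are
# capitalised; matching must cross those conventions while outputs keep the
# casing found in the input matrix.
norm_symbol <- function(x) toupper(trimws(as.character(x)))

# Run `code` under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Abort with a consistent error class so callers can test error categories.
lr_abort <- function(msg, class = "lrnet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
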