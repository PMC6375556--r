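# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed + offset`,
# restoring the caller's RNG afterwards. Fixed per-component offsets keep
# the draws of one generator independent of whether another ran first.
with_stream <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required columns: ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

predictor_names <- function() {
  c("sift", "polyphen", "provean", "mutation_taster", "mutation_assessor", "lrt")
}
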