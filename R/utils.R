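# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the current RNG stream). Restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, kept below 2^31.
# Arithmetic in doubles (exact well past 2^31) to avoid integer overflow.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 1103 + as.numeric(i) * 12289) %% 2147483647)
}

# sample() without the length-1 surprise
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
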