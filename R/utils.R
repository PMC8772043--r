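# Internal helpers shared across modules.

# Canonical key for an unordered gene pair. \x1f (unit separator) cannot occur
# in whitespace-stripped gene identifiers read by this package.
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\x1f")
}

directed_key <- function(u, v) paste(u, v, sep = "\x1f")

split_pair_key <- function(key) {
  parts <- strsplit(key, "\x1f", fixed = TRUE)
  data.frame(
    u = vapply(parts, `[`, character(1), 1L),
    v = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. A NULL seed leaves the global stream alone.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic fan-out of one user-facing seed into per-stage seeds
# (seed + stage offset, kept inside the 32-bit integer range).
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + stage) %% 2147483646L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
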