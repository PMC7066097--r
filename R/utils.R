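# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current stream".
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Draw `n` integer sub-seeds (< 2^31) from the current RNG stream.
.drawSeeds <- function(n) sample.int(.Machine$integer.max, n)

.rowNorms <- function(m) sqrt(rowSums(m^2))

.vnorm <- function(v) sqrt(sum(v^2))

# Column indices in the flattened 3K layout for position indices `j`:
# component c of position j sits at column 3*(j-1)+c (x, y, z interleaved).
.componentCols <- function(j) {
  rep(3L * (j - 1L), each = 3L) + rep.int(1:3, length(j))
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
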