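# Seed plumbing: a counter-based 32-bit mix so per-clip seeds depend only
# on (master seed, counter), never on generation order, plus a local
# set.seed wrapper that restores the caller's RNG state.

# 32-bit unsigned multiply (mod 2^32) without overflowing doubles:
# split one operand into 16-bit halves.
.mul32 <- function(a, b) {
  a <- a %% 4294967296; b <- b %% 4294967296
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536
  (lo + hi * 65536) %% 4294967296
}

# xor of two values in [0, 2^32) held as doubles (bitwXor only takes
# 32-bit signed integers, so work in 16-bit halves).
.xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo + hi * 65536
}

.xorshift32 <- function(x, k) {
  .xor32(x %% 4294967296, (x %% 4294967296) %/% 2^k)
}

#' Derive a child seed from a master seed and a counter
#'
#' Counter-based seed derivation (a splitmix-style 32-bit finalizer), so
#' the seed of clip `i` depends only on `(masterSeed, i)` and never on
#' how many clips were generated before it.
#'
#' @param masterSeed integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in \[0, 2^31 - 1\].
#' @examples
#' deriveSeed(42, 0:3)
#' @export
deriveSeed <- function(masterSeed, counter) {
  vapply(counter, function(ct) {
    x <- (as.numeric(masterSeed) + .mul32(as.numeric(ct) + 1, 2654435769)) %%
      4294967296
    x <- .mul32(.xorshift32(x, 16), 2246822519)
    x <- .mul32(.xorshift32(x, 13), 3266489917)
    x <- .xorshift32(x, 16)
    as.integer(x %% 2147483648)
  }, integer(1))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
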