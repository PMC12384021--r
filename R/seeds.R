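# Deterministic child-seed derivation. Every dataset element and every
# internal RNG stream gets its own seed via a 32-bit integer mixing function
# (xxHash-style avalanche), so streams are independent of draw order and of
# the global RNG state.

bitxor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

mul32 <- function(a, b) {
  al <- a %% 65536
  ah <- (a - al) / 65536
  (al * b + ((ah * b) %% 65536) * 65536) %% 4294967296
}

#' Derive a child RNG seed from a parent seed and an index
#'
#' Applies a 32-bit multiply-xorshift avalanche to the pair `(seed, i)`.
#' Used wherever the package needs per-item reproducible randomness (one
#' stream per generated sample, per training epoch, per augmentation call)
#' without consuming a shared global stream.
#'
#' @param seed Integer parent seed.
#' @param i Nonnegative integer stream index.
#' @return An integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @export
child_seed <- function(seed, i) {
  x <- (seed %% 4294967296 + mul32(i %% 4294967296, 2654435769)) %% 4294967296
  x <- bitxor32(x, floor(x / 65536))
  x <- mul32(x, 2246822519)
  x <- bitxor32(x, floor(x / 8192))
  x <- mul32(x, 3266489917)
  x <- bitxor32(x, floor(x / 65536))
  as.integer(x %% 2147483648)
}

# A self-contained RNG stream that saves/restores the global .Random.seed
# around each draw, so package randomness never perturbs user code.
make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  glob <- globalenv()
  saved <- get0(".Random.seed", envir = glob, inherits = FALSE)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = glob)
  if (is.null(saved)) {
    rm(".Random.seed", envir = glob)
  } else {
    assign(".Random.seed", saved, envir = glob)
  }
  e$draw <- function(f) {
    saved <- get0(".Random.seed", envir = glob, inherits = FALSE)
    assign(".Random.seed", e$state, envir = glob)
    out <- f()
    e$state <- get(".Random.seed", envir = glob)
    if (is.null(saved)) {
      rm(".Random.seed", envir = glob)
    } else {
      assign(".Random.seed", saved, envir = glob)
    }
    out
  }
  e$unif <- function(n = 1L, min = 0, max = 1) e$draw(function() runif(n, min, max))
  e$norm <- function(n = 1L, mean = 0, sd = 1) e$draw(function() rnorm(n, mean, sd))
  e$sample_int <- function(n) e$draw(function() sample.int(n))
  e
}

# run f() under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, f) {
  glob <- globalenv()
  saved <- get0(".Random.seed", envir = glob, inherits = FALSE)
  on.exit({
    if (is.null(saved)) {
      if (exists(".Random.seed", envir = glob, inherits = FALSE))
        rm(".Random.seed", envir = glob)
    } else {
      assign(".Random.seed", saved, envir = glob)
    }
  })
  set.seed(seed)
  f()
}
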