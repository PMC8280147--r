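# Seed plumbing shared by the cohort generator and the validation regimens.
# All seeded operations run inside with_local_seed() so that (a) results
# depend only on the seed argument, never on ambient RNG state, and (b) a
# call never disturbs the caller's RNG stream.

#' Evaluate an expression under a local, restorable RNG state
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# -- 32-bit arithmetic on doubles (R has no unsigned 32-bit integers) --------

two32 <- 4294967296

mul32 <- function(a, b) {
  # (a * b) mod 2^32 without double overflow: split a into 16-bit halves
  al <- a %% 65536
  ah <- (a - al) / 65536
  (al * b + ((ah * b) %% 65536) * 65536) %% two32
}

xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(as.integer(al), as.integer(bl)) +
    bitwXor(as.integer(ah), as.integer(bh)) * 65536
}

shr32 <- function(a, k) floor(a / 2^k)

splitmix32 <- function(x) {
  x <- (x + 2654435769) %% two32           # golden-ratio increment
  z <- x
  z <- xor32(z, shr32(z, 16))
  z <- mul32(z, 2246822507)                # 0x85EBCA6B
  z <- xor32(z, shr32(z, 13))
  z <- mul32(z, 3266489909)                # 0xC2B2AE35
  z <- xor32(z, shr32(z, 16))
  z
}

#' Derive a reproducible sub-seed from (seed, index)
#'
#' Splitmix-style avalanche hash so that sub-streams for different indices
#' are effectively independent. Result fits in a signed 32-bit integer as
#' required by [set.seed()]. `derive_seed(seed, 0) == seed` so that a single
#' repeat of a repeated regimen reduces exactly to the unrepeated one.
#'
#' @param seed outer integer seed.
#' @param index nonnegative integer stream index.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(length(seed) == 1, length(index) == 1, index >= 0)
  if (index == 0) {
    return(as.integer(abs(seed) %% 2147483647))
  }
  h <- splitmix32((abs(seed) %% two32))
  h <- splitmix32((h + index) %% two32)
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
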