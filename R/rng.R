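# Counter-based uniform random streams on 32-bit integer hashing.
#
# Every stochastic component of the package (outline jitter, default
# senescence specs, per-leaf Markov sampling) draws from these streams so
# that results are a pure function of (seed, unit, step), independent of
# evaluation order, and never touch R's global .Random.seed.
#
# Unsigned 32-bit words are carried in doubles (exact below 2^53);
# multiplication is done in 16-bit limbs so products never lose precision.

TWO16 <- 65536
TWO32 <- 4294967296

u32_wrap <- function(x) x %% TWO32

u32_xor <- function(a, b) {
  ah <- a %/% TWO16
  al <- a %% TWO16
  bh <- b %/% TWO16
  bl <- b %% TWO16
  bitwXor(as.integer(ah), as.integer(bh)) * TWO16 +
    bitwXor(as.integer(al), as.integer(bl))
}

# (a * b) mod 2^32 with a, b in [0, 2^32)
u32_mul <- function(a, b) {
  ah <- a %/% TWO16
  al <- a %% TWO16
  bh <- b %/% TWO16
  bl <- b %% TWO16
  (((ah * bl + al * bh) %% TWO16) * TWO16 + al * bl) %% TWO32
}

u32_xorshift_right <- function(z, k) u32_xor(z, z %/% 2^k)

# lowbias32-style finalizer: strong avalanche, cheap to vectorize.
mix32 <- function(z) {
  z <- u32_wrap(z)
  z <- u32_xorshift_right(z, 16)
  z <- u32_mul(z, 0x7feb352d)
  z <- u32_xorshift_right(z, 15)
  z <- u32_mul(z, 0x846ca68b)
  u32_xorshift_right(z, 16)
}

#' Deterministic uniform draws keyed by (seed, unit, step)
#'
#' Returns one uniform variate in (0, 1) per element of `unit` (recycled
#' against `step`). Draws are reproducible and independent of the order in
#' which units are evaluated, which keeps population simulations
#' order-independent.
#'
#' @param seed Integer master seed.
#' @param unit Integer vector identifying the stream (e.g. leaf id).
#' @param step Integer counter within the stream (e.g. epoch).
#' @return Numeric vector of uniforms in (0, 1).
#' @keywords internal
hash_uniform <- function(seed, unit, step = 0) {
  z <- mix32(u32_wrap(seed))
  z <- mix32(u32_wrap(z + unit))
  z <- mix32(u32_wrap(z + step))
  (z + 0.5) / TWO32
}
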