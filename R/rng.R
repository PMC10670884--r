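# Counter-based uniform random numbers.
#
# Every stochastic quantity in the simulator is a deterministic hash of
# (seed, purpose, counter, woman): the draw does not depend on how many draws
# came before it, so natural-history streams are identical across screening
# regimens (common random numbers) and cohort aggregation is order-independent.
# The mixer is the 32-bit MurmurHash3 finalizer, applied twice over the chained
# key components. All arithmetic is done on doubles representing uint32 values
# (exact: intermediates stay below 2^53).

.M32 <- 4294967296 # 2^32

# (a * b) mod 2^32 via 16-bit limbs, exact in double precision
.mul32 <- function(a, b) {
  al <- a %% 65536
  ah <- (a - al) / 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% .M32
}

# bitwise xor on uint32-valued doubles (halved so bitwXor never sees >= 2^31)
.xor32 <- function(a, b) {
  al <- a %% 65536
  bl <- b %% 65536
  bitwXor((a - al) / 65536, (b - bl) / 65536) * 65536 + bitwXor(al, bl)
}

.shr32 <- function(x, n) (x - x %% 2^n) / 2^n

# MurmurHash3 32-bit finalizer: bijective on uint32, full avalanche
.fmix32 <- function(x) {
  x <- .xor32(x, .shr32(x, 16))
  x <- .mul32(x, 2246822507) # 0x85EBCA6B
  x <- .xor32(x, .shr32(x, 13))
  x <- .mul32(x, 3266489909) # 0xC2B2AE35
  .xor32(x, .shr32(x, 16))
}

# purpose tags for the simulator's streams
.rng_purpose <- c(
  onset = 0L, insitu_class = 1L, subtype = 2L, growth = 3L,
  insitu_prog = 4L, nodal = 5L, distant = 6L, surfacing = 7L,
  other_death = 8L, cure = 9L, surv_time = 10L, participation = 11L,
  detect = 12L, fp = 13L, biopsy = 14L
)

# scalar key for (seed, purpose, counter); vectorized draws then fold in women
.rng_base <- function(seed, purpose, counter = 0) {
  b <- .fmix32(.xor32(seed %% .M32, .mul32(purpose + 1, 2654435761)))
  .fmix32(.xor32(b, .mul32(counter %% .M32 + 1, 2246822519)))
}

.rng_wkey <- function(woman_id) .mul32(woman_id %% .M32 + 1, 2654435789)

.rng_u_keyed <- function(base, wkey) {
  (.fmix32(.fmix32(.xor32(base, wkey))) + 0.5) / .M32
}

#' Counter-based uniform deviates
#'
#' Deterministic uniforms on (0, 1) keyed by `(seed, purpose, counter,
#' woman_id)`. The same key always yields the same deviate, regardless of call
#' order, which is what makes common random numbers across screening regimens
#' and reproducible per-woman histories possible.
#'
#' @param seed Integer master seed.
#' @param woman_id Integer vector of woman indices (0-based); the draw is
#'   vectorized over this argument.
#' @param purpose Character stream tag (one of `"onset"`, `"insitu_class"`,
#'   `"subtype"`, `"growth"`, `"insitu_prog"`, `"nodal"`, `"distant"`,
#'   `"surfacing"`, `"other_death"`, `"cure"`, `"surv_time"`,
#'   `"participation"`, `"detect"`, `"fp"`, `"biopsy"`) or a non-negative
#'   integer for ad-hoc streams.
#' @param counter Non-negative integer sub-counter (e.g. the year or screen
#'   age of the draw).
#' @return Numeric vector of uniforms in (0, 1), one per `woman_id`.
#' @examples
#' rng_uniform(1, 0:4, "onset")
#' @export
rng_uniform <- function(seed, woman_id, purpose = "onset", counter = 0) {
  if (is.character(purpose)) {
    purpose <- .rng_purpose[[match.arg(purpose, names(.rng_purpose))]]
  }
  stopifnot(length(seed) == 1, length(counter) == 1, purpose >= 0, counter >= 0)
  .rng_u_keyed(.rng_base(seed, purpose, counter), .rng_wkey(woman_id))
}
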