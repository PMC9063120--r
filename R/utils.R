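# Internal numeric helpers shared across modules.

# Large Mersenne prime; all substructure identifiers live in [0, HASH_MOD).
# 31 * HASH_MOD < 2^53, so the polynomial hash below is exact in doubles.
HASH_MOD <- 2147483647

# Deterministic polynomial rolling hash of an integer vector.
hash_int_vec <- function(v) {
  h <- 17
  for (x in v) {
    h <- (h * 31 + (x %% HASH_MOD)) %% HASH_MOD
  }
  h
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax, shifted for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Clamped log for cross-entropy terms.
safe_log <- function(p, eps = 1e-12) log(pmax(p, eps))

# Add a bias row-vector to every row of a matrix.
add_bias <- function(z, b) sweep(z, 2L, b, "+")

`%||%` <- function(a, b) if (is.null(a)) b else a

# R's Mersenne-Twister seeding leaves consecutive integer seeds with
# heavily overlapping sample() streams (seed k's draws reappear shifted in
# seed k+1). Every entry point that seeds the RNG therefore passes the
# user-visible seed through two Lehmer rounds first; all products stay
# below 2^53, so the map is exact in doubles and fully deterministic.
scramble_seed <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  s <- (s * 48271 + 11) %% 2147483647
  s <- (s * 69621 + 7) %% 2147483647
  as.integer(s)
}

set_seed_scrambled <- function(seed) set.seed(scramble_seed(seed))
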