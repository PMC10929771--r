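# Internal helpers shared across modules.

# Deterministic stream derivation on the MINSTD lattice. Both factors keep the
# intermediate products below 2^53 so the arithmetic is exact in doubles.
minstd_mix <- function(x) {
  x <- x %% 2147483647
  ((x * 48271) %% 2147483647)
}

# Derive a 32-bit-safe seed for one (seed, cycle, decision) slot. Identical
# across strategy arms by construction, which is what gives the engine its
# common-random-numbers property.
derive_seed <- function(seed, cycle, decision) {
  a <- minstd_mix(seed + 1)
  b <- (a + cycle * 100003 + decision * 1009) %% 2147483647
  as.integer(minstd_mix(b) %% 2147483646 + 1)
}

# Uniform draws for one decision slot, aligned to cohort row order. Dead
# individuals still consume their position so arms stay synchronised.
# Callers are responsible for preserving the global RNG state (the engine
# wraps each cycle in withr::with_preserve_seed()).
cycle_uniforms <- function(seed, cycle, decision, n) {
  set.seed(derive_seed(seed, cycle, decision))
  runif(n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1] (got %g).", name, x))
  }
  invisible(x)
}

# Fingerprint used to verify that two runs share a cohort.
cohort_fingerprint <- function(cohort) {
  rlang::hash(list(
    cohort$id, cohort$age, cohort$sex, cohort$quintile,
    round(cohort$income, 9), cohort$state
  ))
}
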