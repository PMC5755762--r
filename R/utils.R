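# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the single user-facing seed. Offsets are
# fixed so that every stage consumes an independent, reproducible stream.
# Result is kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + stage * 1299721) %% 2147483647)
}

# Population z-score (n denominator). A constant vector maps to all zeros.
# Optionally fit the centre/spread on a subset (e.g. artifact-free epochs)
# while transforming every value.
z_pop <- function(x, fit = rep(TRUE, length(x))) {
  mu <- mean(x[fit])
  s <- sqrt(mean((x[fit] - mu)^2))
  # spread at floating-point noise level counts as constant
  if (!is.finite(s) || s <= 1e-10 * max(abs(mu), 1e-300)) {
    return(rep(0, length(x)))
  }
  (x - mu) / s
}

# Next length >= n whose only prime factors are 2 and 5 (fast for R's FFT).
next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    while (k %% 2 == 0) k <- k / 2
    while (k %% 5 == 0) k <- k / 5
    if (k == 1) {
      return(m)
    }
    m <- m + 1
  }
}

# Squared magnitude response of a zero-phase (forward-backward) Butterworth
# band-pass of analog order `order`, evaluated at frequencies f (Hz). The
# forward-backward pass squares the one-way magnitude, hence the power of
# 2 * order in the one-way response and the final square.
butter_band_weight <- function(f, low, high, order = 4) {
  w <- numeric(length(f))
  pos <- f > 0
  fp <- f[pos]
  ratio <- (fp^2 - low * high) / (fp * (high - low))
  one_way_sq <- 1 / (1 + ratio^(2 * order))
  w[pos] <- one_way_sq^2
  w
}

state_levels_4 <- c("WKL", "REM", "NREM", "WKB")
state_levels_3 <- c("WK", "NREM", "REM")
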