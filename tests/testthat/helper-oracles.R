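# Independent oracles kept deliberately separate from the package code
# paths they audit.

# Hill response, second implementation (direct power form).
oracle_hill <- function(s, threshold, k) {
  ifelse(s == 0, 0, s^k / (s^k + threshold^k))
}

# Exhaustive lattice enumeration by triple loop (grid-classification oracle).
oracle_grid_count <- function(resolution, phi, threshold) {
  ax <- seq(0, 1, length.out = resolution)
  count <- 0L
  for (a in ax) for (d in ax) for (cc in ax)
    if (phi * a * d * cc >= threshold) count <- count + 1L
  count
}

# Random valid readiness states under a fixed seed.
random_states <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(A = runif(n), D = runif(n), C = runif(n), phi = runif(n))
}
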