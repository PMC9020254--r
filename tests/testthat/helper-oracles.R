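# Independent oracles used to cross-check the samplers and the
# trapped-regime geometry.  Deliberately written with different algorithms
# than the implementations they test.

# Rayleigh cosine by rejection sampling from the density (3/8)(1 + mu^2)
# (envelope: uniform on [-1, 1] with max density 3/4).
rayleigh_rejection_oracle <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2 * (n - length(out))
    x <- runif(m, -1, 1)
    keep <- runif(m, 0, 0.75) < (3 / 8) * (1 + x^2)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# Maximum attainable polar angle in layer j of a non-scattering slab, found
# by tracing the Snell invariant of grazing-to-normal external rays from
# both faces through the stack, with total internal reflection blocking any
# interface where the invariant exceeds the next index.
theta_max_ray_oracle <- function(n_layers, ne, j, n_theta = 20001) {
  iota <- ne * sin(seq(0, pi / 2, length.out = n_theta))  # Snell invariants
  reaches_from <- function(path_indices) {
    if (length(path_indices) == 0) rep(TRUE, length(iota))
    else iota < min(path_indices) | abs(iota - min(path_indices)) < 1e-12
  }
  M <- length(n_layers)
  ok_top <- reaches_from(n_layers[seq_len(j - 1)])
  ok_bot <- reaches_from(if (j < M) n_layers[(j + 1):M] else numeric(0))
  sin_j <- iota / n_layers[j]
  sin_max <- max(sin_j[ok_top | ok_bot])
  asin(min(1, sin_max))
}

# empirical mean with its standard error
mc_mean_se <- function(x) {
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

expect_within_se <- function(est, se, truth, n_se = 4) {
  expect_lt(abs(est - truth), n_se * se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
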