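# Independent oracles and small fixture builders used across the suite.

# Brute-force O(N^2)-style DFT component magnitude at period T: computes the
# projection sums term by term, independently of the package's vectorized
# scorer.
dft_component_oracle <- function(x, t, period) {
  C <- 0; S <- 0
  for (i in seq_along(x)) {
    C <- C + x[i] * cos(2 * pi * t[i] / period)
    S <- S + x[i] * sin(2 * pi * t[i] / period)
  }
  sqrt(C^2 + S^2)
}

# Closed-form phase of the T-periodic component of x (atan2 of the two
# projection sums), on [0, T).
phase_oracle <- function(x, t, period = 24) {
  C <- sum(x * cos(2 * pi * t / period))
  S <- sum(x * sin(2 * pi * t / period))
  (atan2(S, C) * period / (2 * pi)) %% period
}

# Cosine expression profile peaking at `phase`, baseline b, rel. amplitude a.
cosine_profile <- function(t, phase, baseline = 100, rel_amp = 0.4) {
  baseline * (1 + rel_amp * cos(2 * pi * (t - phase) / 24))
}

# Circular distance between two phases on a 24-h cycle.
phase_dist <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Exact mean unordered shortest path + mean local clustering by brute force
# (matrix-power BFS and triangle counting) for small graphs.
brute_force_topology <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A == 1] <- 1
  reach <- A
  k <- 1
  while (k < n) {
    reach <- (reach %*% A > 0) * 1
    k <- k + 1
    D[D == Inf & reach == 1] <- k
  }
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k_i <- length(nb)
    if (k_i < 2) return(0)
    sum(A[nb, nb]) / 2 / (k_i * (k_i - 1) / 2)
  }, numeric(1))
  finite <- D[upper.tri(D)]
  list(mean_path = mean(finite[is.finite(finite)]), clustering = cc)
}
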