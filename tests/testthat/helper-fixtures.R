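# Shared fixtures: tiny grid-code configs, random PSD matrices, and the
# brute-force subset-enumeration oracle for the elementary DPP expectation.

tiny_config <- function(nf = 2L, np = 4L) {
  grid_code_config(n_frequencies = nf, n_phases = np,
                   base_frequency = 0.05 * 2 * pi, space_extent = 100L)
}

random_psd <- function(n, seed, jitter = 1e-6) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * n), 2 * n, n)
  crossprod(X) / (2 * n) + jitter * diag(n)
}

# Independent oracle: expectation of det(V_u) under Bernoulli(w) inclusion,
# computed by explicit enumeration of all 2^N subsets.
enum_dpp_expectation <- function(w, V) {
  n <- length(w)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    u <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    p <- prod(w[u]) * prod(1 - w[setdiff(seq_len(n), u)])
    d <- if (length(u)) det(V[u, u, drop = FALSE]) else 1
    total <- total + p * d
  }
  total
}

# Block-diagonal toy kernel with given per-block matrices.
block_kernel <- function(...) {
  blocks <- list(...)
  n <- sum(vapply(blocks, nrow, integer(1)))
  V <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    V[idx, idx] <- b
    at <- at + nrow(b)
  }
  V
}
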