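## Alternative position embeddings used by the ablation models: one-hot and
## smoothed one-hot ("place cell") codes over a bounded integer square, plus
## the small feedforward encoders that sit between such embeddings and the
## scorer.

#' One-hot and smoothed one-hot embedders
#'
#' `onehot_embedder(extent)` maps a 2D integer point (x, y) with
#' coordinates in `[0, extent - 1]` to a flattened `extent^2` indicator
#' vector. `smoothed_onehot_embedder(extent, sd)` replaces the indicator
#' with the product of two discretized Gaussian bumps of standard deviation
#' `sd` centred on the point (a place-cell-like code). Each per-dimension
#' bump is normalized to unit sum, so every embedding row sums to 1
#' regardless of location, and the code converges to the one-hot embedding
#' as `sd -> 0`.
#'
#' @param extent side length of the covered square.
#' @param sd standard deviation of the Gaussian bump, in grid units.
#' @return function(points) -> n x extent^2 matrix.
#' @export
onehot_embedder <- function(extent) {
  smoothed_onehot_embedder(extent, sd = 0)
}

#' @rdname onehot_embedder
#' @export
smoothed_onehot_embedder <- function(extent, sd) {
  extent <- as.integer(extent)
  pos <- 0:(extent - 1L)
  bump <- function(center) {
    if (sd <= 0) {
      v <- as.numeric(pos == center)
    } else {
      v <- stats::dnorm(pos, mean = center, sd = sd)
    }
    v / sum(v)
  }
  function(points) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
    n <- nrow(points)
    out <- matrix(0, n, extent * extent)
    for (i in seq_len(n)) {
      out[i, ] <- as.vector(outer(bump(points[i, 1]), bump(points[i, 2])))
    }
    out
  }
}

## Three-layer feedforward encoder applied independently to every stimulus
## vector: two hidden layers with rectifier nonlinearities and an output
## layer that is linear (TCN baseline) or sigmoidal (ablation encoder).

mlp_encoder <- function(input_dim, hidden, out_dim = hidden,
                        out_activation = c("linear", "sigmoid"), seed = 0L) {
  out_activation <- match.arg(out_activation)
  u <- function(nr, nc) {
    k <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -k, k), nr, nc)
  }
  params <- with_seed(seed, list(
    W1 = u(input_dim, hidden), b1 = numeric(hidden),
    W2 = u(hidden, hidden), b2 = numeric(hidden),
    W3 = u(hidden, out_dim), b3 = numeric(out_dim)
  ))
  structure(
    list(params = params, input_dim = input_dim, hidden = hidden,
         out_dim = out_dim, out_activation = out_activation, seed = seed),
    class = "mlp_encoder"
  )
}

mlp_forward <- function(enc, X, keep_cache = FALSE) {
  p <- enc$params
  B <- nrow(X)
  h1 <- pmax(X %*% p$W1 + matrix(p$b1, B, length(p$b1), byrow = TRUE), 0)
  h2 <- pmax(h1 %*% p$W2 + matrix(p$b2, B, length(p$b2), byrow = TRUE), 0)
  z3 <- h2 %*% p$W3 + matrix(p$b3, B, length(p$b3), byrow = TRUE)
  y <- if (enc$out_activation == "sigmoid") sigmoid(z3) else z3
  list(y = y, cache = if (keep_cache) list(X = X, h1 = h1, h2 = h2, y = y) else NULL)
}

mlp_backward <- function(enc, cache, dY) {
  p <- enc$params
  dz3 <- if (enc$out_activation == "sigmoid") dY * cache$y * (1 - cache$y) else dY
  dh2 <- (dz3 %*% t(p$W3)) * (cache$h2 > 0)
  dh1 <- (dh2 %*% t(p$W2)) * (cache$h1 > 0)
  list(
    grads = list(
      W1 = crossprod(cache$X, dh1), b1 = colSums(dh1),
      W2 = crossprod(cache$h1, dh2), b2 = colSums(dh2),
      W3 = crossprod(cache$h2, dz3), b3 = colSums(dz3)
    ),
    dX = dh1 %*% t(p$W1)
  )
}

## Temporal context normalization: z-score each feature across the temporal
## positions of one sequence. X is a list of T matrices (B x F).
tcn_eps <- 1e-8

tcn_forward <- function(X, keep_cache = FALSE) {
  Tn <- length(X)
  mu <- Reduce(`+`, X) / Tn
  v <- Reduce(`+`, lapply(X, function(x) (x - mu)^2)) / Tn
  inv <- 1 / sqrt(v + tcn_eps)
  Y <- lapply(X, function(x) (x - mu) * inv)
  list(Y = Y, cache = if (keep_cache) list(Y = Y, inv = inv, Tn = Tn) else NULL)
}

tcn_backward <- function(dY, cache) {
  Tn <- cache$Tn
  m1 <- Reduce(`+`, dY) / Tn
  m2 <- Reduce(`+`, mapply(function(d, y) d * y, dY, cache$Y,
                           SIMPLIFY = FALSE)) / Tn
  mapply(function(d, y) cache$inv * (d - m1 - y * m2),
         dY, cache$Y, SIMPLIFY = FALSE)
}
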