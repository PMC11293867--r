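#' Build the attention kernel from training-region activations
#'
#' Constructs the positive semidefinite matrix V over grid cells whose
#' principal minors drive the DPP attentional objective. Two forms are
#' available:
#'
#' * `"quality_diversity"` (default): V = diag(sqrt(wm * m)) K
#'   diag(sqrt(wm * m)) + eps I, where m are the per-cell variances of the
#'   activations over the training region and K is a Gaussian similarity,
#'   `K[i, j] = exp(-b * d2[i, j])`, with `d2` the squared Euclidean distance
#'   between the unit-norm z-scored activation profiles of cells i and j
#'   (so `d2 = 2 (1 - cor)` and constant cells get the zero profile).
#'   High-variance cells contribute large diagonal "quality"; correlated
#'   cells produce near-singular minors, shrinking the determinant.
#' * `"covariance"`: the empirical covariance of the activations plus eps I.
#'
#' Both forms are PSD up to the jitter and carry the same qualitative
#' structure: determinants of within-frequency blocks are large when the
#' block's cells are individually variable and mutually decorrelated over
#' the training region.
#'
#' @param activations numeric n_points x n_cells matrix of embeddings over
#'   the training region (n_points >= 2).
#' @param wm quality weight multiplying the per-cell variances.
#' @param b similarity bandwidth of the Gaussian kernel.
#' @param form kernel form, `"quality_diversity"` or `"covariance"`.
#' @param eps diagonal jitter added for numerical positive definiteness.
#' @return object of class `attention_kernel`: list with the matrix `V`,
#'   per-cell variances `m`, and the construction metadata.
#' @export
build_kernel <- function(activations, wm = 1, b = 0.1,
                         form = c("quality_diversity", "covariance"),
                         eps = 1e-8) {
  form <- match.arg(form)
  S <- as.matrix(activations)
  if (nrow(S) < 2L) stop("need at least 2 points to estimate variances")
  stopifnot_finite(S, "activations")
  n <- nrow(S)
  m <- apply(S, 2L, stats::var)
  if (form == "covariance") {
    V <- stats::cov(S)
  } else {
    # unit-norm z-scored profiles: constant cells -> zero profile
    ctr <- sweep(S, 2L, colMeans(S))
    nrm <- sqrt(colSums(ctr^2))
    Z <- sweep(ctr, 2L, pmax(nrm, .Machine$double.eps), "/")
    Z[, nrm == 0] <- 0
    G <- crossprod(Z)
    sq <- diag(G)
    d2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
    K <- exp(-b * d2)
    s <- sqrt(pmax(wm * m, 0))
    V <- K * tcrossprod(s)
  }
  V <- (V + t(V)) / 2
  diag(V) <- diag(V) + eps
  structure(
    list(V = V, m = m, wm = wm, b = b, form = form, eps = eps,
         n_points = n),
    class = "attention_kernel"
  )
}

#' @export
print.attention_kernel <- function(x, ...) {
  cat(sprintf(
    "attention kernel (%s): %d x %d from %d points (wm = %g, b = %g)\n",
    x$form, nrow(x$V), ncol(x$V), x$n_points, x$wm, x$b
  ))
  invisible(x)
}

kernel_matrix <- function(kernel) {
  if (inherits(kernel, "attention_kernel")) kernel$V else as.matrix(kernel)
}

#' Elementary DPP expectation
#'
#' The closed form `det(diag(w) (V - I) + I)` equals the expectation of the
#' principal-minor determinant `det(V_u)` under independent Bernoulli
#' inclusion of each item i with probability `w[i]` (with `det(V_empty) = 1`).
#' This is the differentiable relaxation of subset selection that the
#' attentional objective maximizes per frequency block.
#'
#' @param w inclusion probabilities in `[0, 1]`, length N.
#' @param V PSD N x N matrix (or an [build_kernel()] result).
#' @return scalar expectation.
#' @export
elementary_dpp_expectation <- function(w, V) {
  V <- kernel_matrix(V)
  n <- length(w)
  if (n != nrow(V)) stop("length(w) must match dim(V)")
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  M <- w * (V - diag(n)) + diag(n) # diag(w) %*% (V - I) + I
  det(M)
}

block_indices <- function(f, np) ((f - 1L) * np + 1L):(f * np)

## log det(diag(w) (Vf - I) + I) for one frequency block; fails loudly on a
## non-positive determinant (signals kernel ill-conditioning).
block_logdet <- function(w, Vf, f = NA) {
  M <- w * (Vf - diag(nrow(Vf))) + diag(nrow(Vf))
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) {
    stop(sprintf("non-positive determinant in frequency block %s", f))
  }
  as.numeric(ld$modulus)
}

#' DPP attentional objective
#'
#' The objective summed over frequency blocks,
#' `Fhat(g) = sum_f log det(diag(sigmoid(g_f)) (V_f - I) + I)`,
#' where `g_f` and `V_f` are the gates and kernel block of frequency f.
#' Maximizing `Fhat` (equivalently minimizing `-Fhat`) attends to cells with
#' high variance and low redundancy over the training region.
#'
#' @param gates numeric vector of pre-sigmoid gate logits, length Nf * Np.
#' @param kernel an [build_kernel()] result (or bare PSD matrix).
#' @param n_frequencies,n_phases block structure (Nf, Np).
#' @return scalar objective in nats.
#' @export
dpp_objective <- function(gates, kernel, n_frequencies, n_phases) {
  V <- kernel_matrix(kernel)
  if (length(gates) != n_frequencies * n_phases ||
      nrow(V) != n_frequencies * n_phases) {
    stop("gates/kernel dimension must equal n_frequencies * n_phases")
  }
  w <- sigmoid(gates)
  total <- 0
  for (f in seq_len(n_frequencies)) {
    idx <- block_indices(f, n_phases)
    total <- total + block_logdet(w[idx], V[idx, idx, drop = FALSE], f)
  }
  total
}

## Analytic gradient of the objective with respect to the gate logits.
## For one block, d/dw_i log det(W) = [(V - I) W^{-1}]_{ii} with
## W = diag(w)(V - I) + I; chain through sigmoid.
dpp_objective_grad <- function(gates, kernel, n_frequencies, n_phases) {
  V <- kernel_matrix(kernel)
  w <- sigmoid(gates)
  grad <- numeric(length(gates))
  for (f in seq_len(n_frequencies)) {
    idx <- block_indices(f, n_phases)
    Vf <- V[idx, idx, drop = FALSE]
    A <- Vf - diag(length(idx))
    W <- w[idx] * A + diag(length(idx))
    gw <- diag(A %*% solve(W))
    grad[idx] <- gw * w[idx] * (1 - w[idx])
  }
  grad
}

#' Optimize attention gates under the DPP objective
#'
#' Starting from all-zero logits (gates at 0.5), performs
#' `epochs * batches_per_epoch` gradient-ascent steps on the objective of
#' [dpp_objective()]. The kernel is fixed throughout; only the gates move.
#' For a fixed kernel the objective is deterministic, so "batches" are
#' simply additional full-gradient steps retained for parity with the
#' two-level training loop.
#'
#' @param kernel an [build_kernel()] result.
#' @param n_frequencies,n_phases block structure.
#' @param epochs number of epochs (NE_DPP).
#' @param batches_per_epoch gradient steps per epoch (Nb).
#' @param lr learning rate.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed integer seed (recorded; optimization is deterministic).
#' @return object of class `dpp_gates`: list with logits `g`, activation
#'   `sigma` = sigmoid(g), the per-step objective `trace`, and settings.
#' @export
optimize_gates <- function(kernel, n_frequencies, n_phases,
                           epochs = 50L, batches_per_epoch = 1L,
                           lr = 1e-3, optimizer = c("adam", "sgd"),
                           seed = 0L) {
  optimizer <- match.arg(optimizer)
  n <- n_frequencies * n_phases
  g <- numeric(n)
  steps <- as.integer(epochs) * as.integer(batches_per_epoch)
  trace <- numeric(steps)
  opt <- adam_state(list(g = g))
  for (s in seq_len(steps)) {
    val <- dpp_objective(g, kernel, n_frequencies, n_phases)
    if (!is.finite(val)) stop(sprintf("objective diverged at step %d", s))
    trace[s] <- val
    grad <- dpp_objective_grad(g, kernel, n_frequencies, n_phases)
    if (optimizer == "adam") {
      upd <- adam_step(opt, list(g = -grad), lr) # ascent
      opt <- upd$state
      g <- g + upd$delta$g
    } else {
      g <- g + lr * grad
    }
  }
  structure(
    list(g = g, sigma = sigmoid(g), trace = trace,
         n_frequencies = n_frequencies, n_phases = n_phases,
         epochs = epochs, batches_per_epoch = batches_per_epoch,
         lr = lr, optimizer = optimizer, seed = seed),
    class = "dpp_gates"
  )
}

#' @export
print.dpp_gates <- function(x, ...) {
  cat(sprintf(
    "DPP attention gates: %d cells (%d x %d), %d steps, Fhat %.4f -> %.4f\n",
    length(x$g), x$n_frequencies, x$n_phases, length(x$trace),
    if (length(x$trace)) x$trace[1] else NA,
    if (length(x$trace)) x$trace[length(x$trace)] else NA
  ))
  invisible(x)
}

#' Select the frequency with maximal within-frequency log-determinant
#'
#' Computes the per-frequency objective `Fhat_f` at the given gates and
#' returns the argmax frequency; exact ties resolve to the lowest index.
#' The selected frequency's phase block is what the scorer receives.
#'
#' @param gates a [optimize_gates()] result or a numeric logit vector.
#' @param kernel an [build_kernel()] result.
#' @param n_frequencies,n_phases block structure.
#' @return object of class `frequency_score`: list with `scores` (length
#'   Nf, nats) and `f_max` (selected frequency index).
#' @export
select_max_frequency <- function(gates, kernel, n_frequencies, n_phases) {
  g <- if (inherits(gates, "dpp_gates")) gates$g else gates
  V <- kernel_matrix(kernel)
  w <- sigmoid(g)
  scores <- vapply(seq_len(n_frequencies), function(f) {
    idx <- block_indices(f, n_phases)
    block_logdet(w[idx], V[idx, idx, drop = FALSE], f)
  }, numeric(1))
  structure(
    list(scores = scores, f_max = which.max(scores)),
    class = "frequency_score"
  )
}

#' @export
print.frequency_score <- function(x, ...) {
  cat("per-frequency log-determinant (nats):\n")
  print(round(x$scores, 4))
  cat(sprintf("selected frequency: %d\n", x$f_max))
  invisible(x)
}
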