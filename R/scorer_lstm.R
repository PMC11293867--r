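## LSTM candidate scorer.
##
## A single-layer LSTM consumes the stimulus sequence for one candidate
## completion (A, B, C, candidate for analogies; A, B, candidate for
## arithmetic), with hidden and cell state re-initialized to zero at the
## start of every sequence. The final hidden state passes through a linear
## layer with one output unit to produce the candidate's score.
##
## Parameters are stored with gate order (input, forget, cell-candidate,
## output) concatenated along columns: W is D x 4H, U is H x 4H.

#' Create an LSTM candidate scorer
#'
#' @param input_dim dimension of each stimulus vector.
#' @param hidden number of hidden units (hidden and cell state size).
#' @param seed integer seed for the uniform fan-in initialization
#'   (U(-1/sqrt(hidden), 1/sqrt(hidden)), the standard scheme for gated
#'   recurrent nets).
#' @return object of class `lstm_scorer`.
#' @export
lstm_scorer <- function(input_dim, hidden = 512L, seed = 0L) {
  input_dim <- as.integer(input_dim)
  hidden <- as.integer(hidden)
  k <- 1 / sqrt(hidden)
  params <- with_seed(seed, list(
    W = matrix(stats::runif(input_dim * 4L * hidden, -k, k), input_dim, 4L * hidden),
    U = matrix(stats::runif(hidden * 4L * hidden, -k, k), hidden, 4L * hidden),
    b = stats::runif(4L * hidden, -k, k),
    w_out = matrix(stats::runif(hidden, -k, k), hidden, 1L),
    b_out = stats::runif(1L, -k, k)
  ))
  structure(
    list(params = params, input_dim = input_dim, hidden = hidden,
         kind = "lstm", seed = seed),
    class = c("lstm_scorer", "scorer")
  )
}

#' @export
print.lstm_scorer <- function(x, ...) {
  cat(sprintf("LSTM scorer: input %d, hidden %d\n", x$input_dim, x$hidden))
  invisible(x)
}

gate_cols <- function(H) {
  list(i = 1:H, f = (H + 1):(2 * H), g = (2 * H + 1):(3 * H),
       o = (3 * H + 1):(4 * H))
}

## Forward pass over a batch of sequences. X is a list of T matrices, each
## B x D (time-major). Returns scores (length B) and, if keep_cache, the
## per-step activations needed for backpropagation.
lstm_forward <- function(scorer, X, keep_cache = FALSE) {
  p <- scorer$params
  H <- scorer$hidden
  Tn <- length(X)
  B <- nrow(X[[1]])
  cols <- gate_cols(H)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Z <- X[[t]] %*% p$W + h %*% p$U + matrix(p$b, B, 4L * H, byrow = TRUE)
    gi <- sigmoid(Z[, cols$i, drop = FALSE])
    gf <- sigmoid(Z[, cols$f, drop = FALSE])
    gg <- tanh(Z[, cols$g, drop = FALSE])
    go <- sigmoid(Z[, cols$o, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    if (keep_cache) {
      cache[[t]] <- list(gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
  }
  scores <- drop(h %*% p$w_out) + p$b_out
  list(scores = scores, h_final = h, cache = cache)
}

## Backward pass. dscores is a length-B vector of gradients of the loss with
## respect to each sequence's score. Returns gradients for every parameter
## and (optionally) with respect to the inputs.
lstm_backward <- function(scorer, X, fwd, dscores, want_dx = FALSE) {
  p <- scorer$params
  H <- scorer$hidden
  Tn <- length(X)
  B <- nrow(X[[1]])
  cols <- gate_cols(H)
  ds <- matrix(dscores, B, 1L)
  grads <- list(
    W = matrix(0, nrow(p$W), ncol(p$W)),
    U = matrix(0, nrow(p$U), ncol(p$U)),
    b = numeric(length(p$b)),
    w_out = t(fwd$h_final) %*% ds,
    b_out = sum(ds)
  )
  dh <- ds %*% t(p$w_out)
  dc <- matrix(0, B, H)
  dX <- if (want_dx) vector("list", Tn) else NULL
  for (t in rev(seq_len(Tn))) {
    cache_t <- fwd$cache[[t]]
    dgo <- dh * cache_t$tc
    dc <- dc + dh * cache_t$go * (1 - cache_t$tc^2)
    dgi <- dc * cache_t$gg
    dgg <- dc * cache_t$gi
    dgf <- dc * cache_t$c_prev
    dc <- dc * cache_t$gf
    dZ <- matrix(0, B, 4L * H)
    dZ[, cols$i] <- dgi * cache_t$gi * (1 - cache_t$gi)
    dZ[, cols$f] <- dgf * cache_t$gf * (1 - cache_t$gf)
    dZ[, cols$g] <- dgg * (1 - cache_t$gg^2)
    dZ[, cols$o] <- dgo * cache_t$go * (1 - cache_t$go)
    grads$W <- grads$W + crossprod(X[[t]], dZ)
    grads$U <- grads$U + crossprod(cache_t$h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dh <- dZ %*% t(p$U)
    if (want_dx) dX[[t]] <- dZ %*% t(p$W)
  }
  list(grads = grads, dX = dX)
}

#' Score candidate sequences with an LSTM
#'
#' Scores each sequence independently: state is re-initialized per sequence,
#' so a candidate's score depends only on its own stimuli.
#'
#' @param scorer an [lstm_scorer()].
#' @param X list of `T` matrices (one per time step), each `B x input_dim`;
#'   or a single `T x input_dim` matrix for one sequence.
#' @return numeric vector of `B` scores.
#' @export
lstm_score <- function(scorer, X) {
  if (is.matrix(X)) X <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  if (!length(X)) stop("empty sequence")
  if (ncol(X[[1]]) != scorer$input_dim) stop("input dimension mismatch")
  lstm_forward(scorer, X)$scores
}
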