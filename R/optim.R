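## Minimal Adam optimizer over a named list of numeric arrays.
## `adam_step` takes gradients of the quantity being *minimized* and returns
## the additive parameter update (already negated), plus the new state.

adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  list(m = zeros, v = zeros, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  delta <- vector("list", length(grads))
  names(delta) <- names(grads)
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    delta[[k]] <- -lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, delta = delta)
}

apply_delta <- function(params, delta) {
  for (k in names(delta)) {
    params[[k]] <- params[[k]] + delta[[k]]
  }
  params
}
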