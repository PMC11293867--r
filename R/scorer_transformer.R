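## Transformer candidate scorer.
##
## Stimuli for one candidate evaluation are presented together as a token
## set: each stimulus vector is projected to `proj_dim` dimensions, layer
## normalized, given a learned positional encoding, and prepended with a
## learned CLS token. A stack of pre-norm blocks
##   r = MHSA(LN(x)) + x;  out = MLP(LN(r)) + r
## transforms the tokens; the CLS output passes through a one-unit linear
## head to give the candidate's score.
##
## Head bookkeeping: queries and keys have width `dk` per head while values
## split the `proj_dim` evenly (`proj_dim / heads` per head), so the
## concatenated head outputs map back to `proj_dim` through W_O.

ln_eps <- 1e-5

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + matrix(b, nrow(X), ncol(X), byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

#' Create a transformer candidate scorer
#'
#' @param input_dim dimension of each stimulus vector.
#' @param n_tokens number of stimulus tokens per candidate evaluation
#'   (4 for analogies, 3 for arithmetic); sets the positional table size.
#' @param layers number of transformer blocks.
#' @param heads attention heads per block.
#' @param dk query/key width per head.
#' @param mlp_hidden hidden width of each block's MLP.
#' @param proj_dim model width (must be divisible by `heads`).
#' @param use_positions add learned positional encodings (disable to obtain
#'   a permutation-invariant scorer).
#' @param seed integer seed for initialization.
#' @return object of class `transformer_scorer`.
#' @export
transformer_scorer <- function(input_dim, n_tokens = 4L, layers = 6L,
                               heads = 8L, dk = 32L, mlp_hidden = 512L,
                               proj_dim = 128L, use_positions = TRUE,
                               seed = 0L) {
  input_dim <- as.integer(input_dim)
  proj_dim <- as.integer(proj_dim)
  heads <- as.integer(heads)
  if (proj_dim %% heads != 0L) stop("proj_dim must be divisible by heads")
  dv <- proj_dim %/% heads
  u <- function(nr, nc) {
    k <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -k, k), nr, nc)
  }
  params <- with_seed(seed, {
    layer_params <- lapply(seq_len(layers), function(l) {
      list(
        ln1_g = rep(1, proj_dim), ln1_b = rep(0, proj_dim),
        Wq = u(proj_dim, heads * dk), Wk = u(proj_dim, heads * dk),
        Wv = u(proj_dim, proj_dim), Wo = u(proj_dim, proj_dim),
        ln2_g = rep(1, proj_dim), ln2_b = rep(0, proj_dim),
        W1 = u(proj_dim, mlp_hidden), b1 = numeric(mlp_hidden),
        W2 = u(mlp_hidden, proj_dim), b2 = numeric(proj_dim)
      )
    })
    list(
      W_in = u(input_dim, proj_dim), b_in = numeric(proj_dim),
      ln_in_g = rep(1, proj_dim), ln_in_b = rep(0, proj_dim),
      pos = u(n_tokens, proj_dim),
      cls = stats::runif(proj_dim, -1 / sqrt(proj_dim), 1 / sqrt(proj_dim)),
      layers = layer_params,
      head_w = u(proj_dim, 1L), head_b = 0
    )
  })
  structure(
    list(params = params, input_dim = input_dim, n_tokens = as.integer(n_tokens),
         layers = as.integer(layers), heads = heads, dk = as.integer(dk),
         dv = dv, mlp_hidden = as.integer(mlp_hidden), proj_dim = proj_dim,
         use_positions = isTRUE(use_positions), kind = "transformer",
         seed = seed),
    class = c("transformer_scorer", "scorer")
  )
}

#' @export
print.transformer_scorer <- function(x, ...) {
  cat(sprintf(
    "transformer scorer: input %d, %d layers, %d heads (dk %d), width %d\n",
    x$input_dim, x$layers, x$heads, x$dk, x$proj_dim
  ))
  invisible(x)
}

## Forward pass. X is a list of n_tokens matrices, each B x input_dim.
transformer_forward <- function(scorer, X, keep_cache = FALSE) {
  p <- scorer$params
  Tn <- length(X)
  B <- nrow(X[[1]])
  P <- scorer$proj_dim
  Hh <- scorer$heads
  dk <- scorer$dk
  dv <- scorer$dv
  sc <- 1 / sqrt(dk)

  in_ln <- vector("list", Tn)
  tok <- vector("list", Tn + 1L)
  tok[[1L]] <- matrix(p$cls, B, P, byrow = TRUE)
  for (t in seq_len(Tn)) {
    proj <- X[[t]] %*% p$W_in + matrix(p$b_in, B, P, byrow = TRUE)
    in_ln[[t]] <- ln_forward(proj, p$ln_in_g, p$ln_in_b)
    tok[[t + 1L]] <- in_ln[[t]]$y +
      if (scorer$use_positions) matrix(p$pos[t, ], B, P, byrow = TRUE) else 0
  }
  S <- Tn + 1L

  layer_cache <- if (keep_cache) vector("list", scorer$layers) else NULL
  for (l in seq_len(scorer$layers)) {
    lp <- p$layers[[l]]
    x_in <- tok
    ln1 <- lapply(tok, ln_forward, g = lp$ln1_g, b = lp$ln1_b)
    Q <- lapply(ln1, function(z) z$y %*% lp$Wq)
    K <- lapply(ln1, function(z) z$y %*% lp$Wk)
    Vv <- lapply(ln1, function(z) z$y %*% lp$Wv)
    # attention weights per (head, query token): B x S
    attw <- vector("list", Hh)
    O <- lapply(seq_len(S), function(t) matrix(0, B, P))
    for (h in seq_len(Hh)) {
      qc <- ((h - 1L) * dk + 1L):(h * dk)
      vc <- ((h - 1L) * dv + 1L):(h * dv)
      attw[[h]] <- vector("list", S)
      for (t in seq_len(S)) {
        sc_mat <- matrix(0, B, S)
        for (t2 in seq_len(S)) {
          sc_mat[, t2] <- rowSums(Q[[t]][, qc, drop = FALSE] *
                                    K[[t2]][, qc, drop = FALSE]) * sc
        }
        aw <- softmax(sc_mat)
        attw[[h]][[t]] <- aw
        acc <- matrix(0, B, dv)
        for (t2 in seq_len(S)) {
          acc <- acc + aw[, t2] * Vv[[t2]][, vc, drop = FALSE]
        }
        O[[t]][, vc] <- acc
      }
    }
    A <- lapply(O, function(o) o %*% lp$Wo)
    r <- mapply(function(a, x) a + x, A, x_in, SIMPLIFY = FALSE)
    ln2 <- lapply(r, ln_forward, g = lp$ln2_g, b = lp$ln2_b)
    hpre <- lapply(ln2, function(z) z$y %*% lp$W1 +
                     matrix(lp$b1, B, scorer$mlp_hidden, byrow = TRUE))
    hact <- lapply(hpre, function(z) pmax(z, 0))
    mlp <- lapply(hact, function(z) z %*% lp$W2 +
                    matrix(lp$b2, B, P, byrow = TRUE))
    tok <- mapply(function(m, rr) m + rr, mlp, r, SIMPLIFY = FALSE)
    if (keep_cache) {
      layer_cache[[l]] <- list(x_in = x_in, ln1 = ln1, Q = Q, K = K, V = Vv,
                               attw = attw, O = O, r = r, ln2 = ln2,
                               hact = hact)
    }
  }
  scores <- drop(tok[[1L]] %*% p$head_w) + p$head_b
  list(scores = scores, cls_out = tok[[1L]],
       cache = if (keep_cache) list(layers = layer_cache, in_ln = in_ln,
                                    X = X, S = S, B = B) else NULL)
}

zero_like_params <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

## Backward pass mirroring transformer_forward. Returns parameter gradients
## with the same nesting as scorer$params.
transformer_backward <- function(scorer, fwd, dscores, want_dx = FALSE) {
  p <- scorer$params
  cache <- fwd$cache
  B <- cache$B
  S <- cache$S
  Tn <- S - 1L
  P <- scorer$proj_dim
  Hh <- scorer$heads
  dk <- scorer$dk
  dv <- scorer$dv
  sc <- 1 / sqrt(dk)
  grads <- zero_like_params(p)

  ds <- matrix(dscores, B, 1L)
  grads$head_w <- crossprod(fwd$cls_out, ds)
  grads$head_b <- sum(ds)
  dtok <- lapply(seq_len(S), function(t) matrix(0, B, P))
  dtok[[1L]] <- ds %*% t(p$head_w)

  for (l in rev(seq_len(scorer$layers))) {
    lp <- p$layers[[l]]
    cl <- cache$layers[[l]]
    dr <- vector("list", S)
    for (t in seq_len(S)) {
      dout <- dtok[[t]]
      # MLP branch
      dhact <- dout %*% t(lp$W2)
      grads$layers[[l]]$W2 <- grads$layers[[l]]$W2 +
        crossprod(cl$hact[[t]], dout)
      grads$layers[[l]]$b2 <- grads$layers[[l]]$b2 + colSums(dout)
      dhpre <- dhact * (cl$hact[[t]] > 0)
      dln2y <- dhpre %*% t(lp$W1)
      grads$layers[[l]]$W1 <- grads$layers[[l]]$W1 +
        crossprod(cl$ln2[[t]]$y, dhpre)
      grads$layers[[l]]$b1 <- grads$layers[[l]]$b1 + colSums(dhpre)
      bl <- ln_backward(dln2y, cl$ln2[[t]], lp$ln2_g)
      grads$layers[[l]]$ln2_g <- grads$layers[[l]]$ln2_g + bl$dg
      grads$layers[[l]]$ln2_b <- grads$layers[[l]]$ln2_b + bl$db
      dr[[t]] <- dout + bl$dX # residual + normalized path
    }
    # attention branch: r = A + x_in, A = O %*% Wo
    dx_in <- dr
    dQ <- lapply(seq_len(S), function(t) matrix(0, B, Hh * dk))
    dK <- lapply(seq_len(S), function(t) matrix(0, B, Hh * dk))
    dV <- lapply(seq_len(S), function(t) matrix(0, B, P))
    for (t in seq_len(S)) {
      dA <- dr[[t]]
      dO <- dA %*% t(lp$Wo)
      grads$layers[[l]]$Wo <- grads$layers[[l]]$Wo +
        crossprod(cl$O[[t]], dA)
      for (h in seq_len(Hh)) {
        qc <- ((h - 1L) * dk + 1L):(h * dk)
        vc <- ((h - 1L) * dv + 1L):(h * dv)
        dOh <- dO[, vc, drop = FALSE]
        aw <- cl$attw[[h]][[t]]
        daw <- matrix(0, B, S)
        for (t2 in seq_len(S)) {
          daw[, t2] <- rowSums(dOh * cl$V[[t2]][, vc, drop = FALSE])
          dV[[t2]][, vc] <- dV[[t2]][, vc] + aw[, t2] * dOh
        }
        dsc_mat <- aw * (daw - rowSums(aw * daw))
        for (t2 in seq_len(S)) {
          dQ[[t]][, qc] <- dQ[[t]][, qc] +
            dsc_mat[, t2] * cl$K[[t2]][, qc, drop = FALSE] * sc
          dK[[t2]][, qc] <- dK[[t2]][, qc] +
            dsc_mat[, t2] * cl$Q[[t]][, qc, drop = FALSE] * sc
        }
      }
    }
    for (t in seq_len(S)) {
      y1 <- cl$ln1[[t]]$y
      dln1y <- dQ[[t]] %*% t(lp$Wq) + dK[[t]] %*% t(lp$Wk) +
        dV[[t]] %*% t(lp$Wv)
      grads$layers[[l]]$Wq <- grads$layers[[l]]$Wq + crossprod(y1, dQ[[t]])
      grads$layers[[l]]$Wk <- grads$layers[[l]]$Wk + crossprod(y1, dK[[t]])
      grads$layers[[l]]$Wv <- grads$layers[[l]]$Wv + crossprod(y1, dV[[t]])
      bl <- ln_backward(dln1y, cl$ln1[[t]], lp$ln1_g)
      grads$layers[[l]]$ln1_g <- grads$layers[[l]]$ln1_g + bl$dg
      grads$layers[[l]]$ln1_b <- grads$layers[[l]]$ln1_b + bl$db
      dx_in[[t]] <- dx_in[[t]] + bl$dX
    }
    dtok <- dx_in
  }

  grads$cls <- colSums(dtok[[1L]])
  dX <- if (want_dx) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    dt <- dtok[[t + 1L]]
    if (scorer$use_positions) {
      grads$pos[t, ] <- grads$pos[t, ] + colSums(dt)
    }
    bl <- ln_backward(dt, cache$in_ln[[t]], p$ln_in_g)
    grads$ln_in_g <- grads$ln_in_g + bl$dg
    grads$ln_in_b <- grads$ln_in_b + bl$db
    grads$W_in <- grads$W_in + crossprod(cache$X[[t]], bl$dX)
    grads$b_in <- grads$b_in + colSums(bl$dX)
    if (want_dx) dX[[t]] <- bl$dX %*% t(p$W_in)
  }
  if (want_dx) attr(grads, "dX") <- dX
  grads
}

#' Score candidate stimuli with a transformer
#'
#' @param scorer a [transformer_scorer()].
#' @param X list of `n_tokens` matrices (one per stimulus position), each
#'   `B x input_dim`; or a single `n_tokens x input_dim` matrix for one
#'   candidate evaluation.
#' @return numeric vector of `B` scores (CLS head output).
#' @export
transformer_score <- function(scorer, X) {
  if (is.matrix(X)) X <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  if (!length(X)) stop("empty stimulus list")
  if (ncol(X[[1]]) != scorer$input_dim) stop("input dimension mismatch")
  transformer_forward(scorer, X)$scores
}
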