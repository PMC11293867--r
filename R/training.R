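## Scorer training engine.
##
## One engine trains every model variant: the scorer (LSTM or transformer)
## always sits on top, and a model-specific "frontend" transforms the raw
## embedding sequences on the way in:
##   plain          - embeddings go straight to the scorer
##   dropout        - one locked 50% dropout mask per sequence, constant
##                    across time steps (inverted scaling; identity at eval)
##   gated          - elementwise sigmoid gates on the embedding, optionally
##                    with an L1 penalty on the gate activations
##   encoder_tcn    - shared feedforward encoder per stimulus, then temporal
##                    context normalization across the sequence
##   encoder_gated  - shared feedforward encoder, then sigmoid gates trained
##                    with the combined loss L_task - lambda * Fhat(g, V)
##                    (V rebuilt from encoder outputs at each epoch start)
## All trainable parameters (scorer, encoder, gates) are updated jointly by
## Adam on the cross-entropy task loss plus any penalty terms.

new_frontend <- function(type = "plain", input_dim = NULL, p = 0.5,
                         l1_lambda = 0, encoder = NULL, dpp_lambda = 0,
                         kernel_inputs = NULL, wm = 1, b = 0.1) {
  fe <- list(type = type, p = p, l1_lambda = l1_lambda,
             encoder = encoder, dpp_lambda = dpp_lambda,
             kernel_inputs = kernel_inputs, wm = wm, b = b, V = NULL)
  if (type %in% c("gated")) fe$g <- numeric(input_dim)
  if (type == "encoder_gated") fe$g <- numeric(encoder$out_dim)
  fe
}

frontend_params <- function(fe) {
  out <- list()
  if (!is.null(fe$g)) out$g <- fe$g
  if (!is.null(fe$encoder)) out$enc <- fe$encoder$params
  out
}

set_frontend_params <- function(fe, params) {
  if (!is.null(params$g)) fe$g <- params$g
  if (!is.null(params$enc)) fe$encoder$params <- params$enc
  fe
}

frontend_needs_dx <- function(fe) {
  fe$type %in% c("gated", "encoder_tcn", "encoder_gated")
}

## Forward transform of a batch. `train` enables dropout sampling (from the
## ambient RNG, so the caller's seed governs it).
frontend_forward <- function(fe, X, train = FALSE) {
  switch(fe$type,
    plain = list(Y = X, cache = NULL),
    dropout = {
      if (train) {
        mask <- matrix(
          stats::rbinom(nrow(X[[1]]) * ncol(X[[1]]), 1L, 1 - fe$p),
          nrow(X[[1]]), ncol(X[[1]])
        ) / (1 - fe$p)
        list(Y = lapply(X, function(x) x * mask), cache = list(mask = mask))
      } else {
        list(Y = X, cache = NULL)
      }
    },
    gated = {
      sg <- sigmoid(fe$g)
      list(Y = lapply(X, function(x) sweep(x, 2L, sg, "*")),
           cache = list(X = X, sg = sg))
    },
    encoder_tcn = {
      encf <- lapply(X, function(x) mlp_forward(fe$encoder, x, keep_cache = TRUE))
      tf <- tcn_forward(lapply(encf, `[[`, "y"), keep_cache = TRUE)
      list(Y = tf$Y, cache = list(encf = encf, tcn = tf$cache))
    },
    encoder_gated = {
      encf <- lapply(X, function(x) mlp_forward(fe$encoder, x, keep_cache = TRUE))
      sg <- sigmoid(fe$g)
      list(Y = lapply(encf, function(e) sweep(e$y, 2L, sg, "*")),
           cache = list(encf = encf, sg = sg))
    },
    stop("unknown frontend type")
  )
}

## Parameter gradients of the frontend given gradients with respect to its
## outputs; includes penalty terms (L1 on gates, -lambda * Fhat).
frontend_backward <- function(fe, cache, dY, n_problems) {
  switch(fe$type,
    plain = list(),
    dropout = list(),
    gated = {
      sg <- cache$sg
      dg_gate <- Reduce(`+`, mapply(function(d, x) colSums(d * x),
                                    dY, cache$X, SIMPLIFY = FALSE))
      dg <- dg_gate * sg * (1 - sg)
      if (fe$l1_lambda > 0) dg <- dg + fe$l1_lambda * sg * (1 - sg)
      list(g = dg)
    },
    encoder_tcn = {
      dEnc <- tcn_backward(dY, cache$tcn)
      acc <- NULL
      for (t in seq_along(dEnc)) {
        bb <- mlp_backward(fe$encoder, cache$encf[[t]]$cache, dEnc[[t]])
        acc <- if (is.null(acc)) bb$grads else
          mapply(`+`, acc, bb$grads, SIMPLIFY = FALSE)
      }
      list(enc = acc)
    },
    encoder_gated = {
      sg <- cache$sg
      dg_gate <- Reduce(`+`, mapply(function(d, e) colSums(d * e$y),
                                    dY, cache$encf, SIMPLIFY = FALSE))
      dg <- dg_gate * sg * (1 - sg)
      if (fe$dpp_lambda > 0 && !is.null(fe$V)) {
        # combined loss L = L_task - lambda * Fhat(g, V): single block
        dg <- dg - fe$dpp_lambda *
          dpp_objective_grad(fe$g, fe$V, 1L, length(fe$g))
      }
      acc <- NULL
      for (t in seq_along(dY)) {
        dE <- sweep(dY[[t]], 2L, sg, "*")
        bb <- mlp_backward(fe$encoder, cache$encf[[t]]$cache, dE)
        acc <- if (is.null(acc)) bb$grads else
          mapply(`+`, acc, bb$grads, SIMPLIFY = FALSE)
      }
      list(g = dg, enc = acc)
    },
    stop("unknown frontend type")
  )
}

## Refresh state at the start of an epoch (encoder-dependent DPP kernel).
frontend_epoch_setup <- function(fe) {
  if (fe$type == "encoder_gated" && fe$dpp_lambda > 0 &&
      !is.null(fe$kernel_inputs)) {
    enc_out <- mlp_forward(fe$encoder, fe$kernel_inputs)$y
    fe$V <- build_kernel(enc_out, wm = fe$wm, b = fe$b)
  }
  fe
}

problem_rows <- function(pidx) {
  rep((pidx - 1L) * 7L, each = 7L) + rep(1:7, length(pidx))
}

## Train a scorer (and frontend) on prepared sequences by Adam on the
## softmax cross-entropy over the 7 candidates of each problem.
train_scorer_engine <- function(scorer, seqs, epochs, batch_size, lr,
                                seed = 0L, frontend = new_frontend("plain"),
                                shuffle = TRUE) {
  n <- seqs$n
  all_params <- list(scorer = scorer$params, fe = frontend_params(frontend))
  theta <- unlist(all_params)
  opt <- adam_state(list(theta = theta))
  losses <- numeric(0)
  want_dx <- frontend_needs_dx(frontend)
  with_seed(derive_seed(seed, 424243L), {
    for (epoch in seq_len(epochs)) {
      frontend <- frontend_epoch_setup(frontend)
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        pidx <- ord[s:min(s + batch_size - 1L, n)]
        nb <- length(pidx)
        rows <- problem_rows(pidx)
        Xb <- lapply(seqs$X, function(m) m[rows, , drop = FALSE])
        tb <- seqs$target[pidx]
        fe_out <- frontend_forward(frontend, Xb, train = TRUE)
        fwd <- scorer_forward(scorer, fe_out$Y, keep_cache = TRUE)
        S <- matrix(fwd$scores, nb, 7L, byrow = TRUE)
        mx <- apply(S, 1L, max)
        lse <- mx + log(rowSums(exp(S - mx)))
        loss <- mean(lse - S[cbind(seq_len(nb), tb)])
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d", epoch))
        }
        losses <- c(losses, loss)
        G <- exp(S - lse)
        G[cbind(seq_len(nb), tb)] <- G[cbind(seq_len(nb), tb)] - 1
        dscores <- as.vector(t(G / nb))
        bwd <- scorer_backward(scorer, fe_out$Y, fwd, dscores, want_dx)
        fe_grads <- frontend_backward(frontend, fe_out$cache, bwd$dX, nb)
        gvec <- unlist(list(scorer = bwd$grads, fe = fe_grads))
        upd <- adam_step(opt, list(theta = gvec), lr)
        opt <- upd$state
        theta <- theta + upd$delta$theta
        all_params <- utils::relist(theta, all_params)
        scorer$params <- all_params$scorer
        frontend <- set_frontend_params(frontend, all_params$fe)
      }
    }
  })
  list(scorer = scorer, frontend = frontend, losses = losses)
}

## Deterministic (evaluation-mode) frontend application.
frontend_apply_eval <- function(fe, X) {
  frontend_forward(fe, X, train = FALSE)$Y
}

#' Evaluate a scorer over named problem-set regions
#'
#' Computes, for each region, the fraction of problems whose
#' highest-probability candidate is the correct completion.
#'
#' @param scorer a trained scorer.
#' @param problem_sets named list of `problem_set` objects (e.g. train, val,
#'   K1..K9).
#' @param embed_fn embedding function, e.g. from [grid_embedder()].
#' @param frontend optional frontend (gates, dropout, encoder) applied in
#'   evaluation mode between embeddings and scorer.
#' @return named numeric vector of accuracies in `[0, 1]`.
#' @export
evaluate_regions <- function(scorer, problem_sets, embed_fn,
                             frontend = NULL) {
  if (!length(problem_sets)) stop("no problem sets to evaluate")
  vapply(problem_sets, function(ps) {
    if (ps$n == 0L) stop("empty problem set")
    seqs <- build_sequences(ps, embed_fn)
    X <- if (is.null(frontend)) seqs$X else frontend_apply_eval(frontend, seqs$X)
    raw <- scorer_forward(scorer, X)$scores
    S <- matrix(raw, seqs$n, 7L, byrow = TRUE)
    mean(max.col(S, ties.method = "first") == seqs$target)
  }, numeric(1))
}
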