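# Independent scalar re-implementation of the gated recurrence used as an
# oracle for the batched LSTM forward pass.
lstm_oracle_score <- function(params, X, H) {
  h <- numeric(H)
  cc <- numeric(H)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(nrow(X))) {
    z <- drop(X[t, ] %*% params$W) + drop(h %*% params$U) + params$b
    i <- sig(z[1:H])
    f <- sig(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)])
    o <- sig(z[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  drop(h %*% params$w_out) + params$b_out
}

test_that("the LSTM matches a step-by-step scalar recurrence", {
  sc <- lstm_scorer(5L, 4L, seed = 1L)
  set.seed(2)
  Xm <- matrix(rnorm(15), 3, 5)
  expect_equal(lstm_score(sc, Xm),
               lstm_oracle_score(sc$params, Xm, 4L),
               tolerance = 1e-12)
})

test_that("LSTM scoring is deterministic with per-sequence state reset", {
  sc <- lstm_scorer(6L, 8L, seed = 3L)
  set.seed(4)
  X <- lapply(1:3, function(t) matrix(rnorm(4 * 6), 4, 6))
  s1 <- lstm_score(sc, X)
  # identical sequences in one batch score identically
  Xdup <- lapply(X, function(m) m[c(1, 1, 2, 3), ])
  sdup <- lstm_score(sc, Xdup)
  expect_equal(sdup[1], sdup[2])
  # rescoring yields the same values (no carried state)
  expect_equal(lstm_score(sc, X), s1)
  # a candidate's score ignores the other sequences in the batch
  Xedit <- lapply(X, function(m) { m[3, ] <- 99; m })
  expect_equal(lstm_score(sc, Xedit)[1], s1[1])
  # all-zero parameters score zero
  sc0 <- sc
  sc0$params <- lapply(sc0$params, function(p) p * 0)
  expect_equal(lstm_score(sc0, X), rep(0, 4))
  expect_error(lstm_score(sc, list()), "empty")
})

test_that("LSTM backward agrees with finite differences", {
  sc <- lstm_scorer(4L, 3L, seed = 5L)
  set.seed(6)
  X <- lapply(1:3, function(t) matrix(rnorm(2 * 4), 2, 4))
  ds <- rnorm(2)
  fwd <- dppa:::lstm_forward(sc, X, keep_cache = TRUE)
  bwd <- dppa:::lstm_backward(sc, X, fwd, ds, want_dx = TRUE)
  loss <- function(p) {
    s2 <- sc; s2$params <- p
    sum(dppa:::lstm_forward(s2, X)$scores * ds)
  }
  eps <- 1e-6
  for (nm in names(sc$params)) {
    for (i in seq_len(min(4, length(sc$params[[nm]])))) {
      p1 <- sc$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- sc$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      expect_equal(as.numeric(bwd$grads[[nm]])[i],
                   (loss(p1) - loss(p2)) / (2 * eps), tolerance = 1e-5)
    }
  }
  x1 <- X; x1[[2]][1, 3] <- x1[[2]][1, 3] + eps
  x2 <- X; x2[[2]][1, 3] <- x2[[2]][1, 3] - eps
  num <- (sum(dppa:::lstm_forward(sc, x1)$scores * ds) -
            sum(dppa:::lstm_forward(sc, x2)$scores * ds)) / (2 * eps)
  expect_equal(bwd$dX[[2]][1, 3], num, tolerance = 1e-5)
})

# Dense single-layer, single-head oracle for the transformer block.
transformer_oracle_scores <- function(sc, X) {
  p <- sc$params
  ln <- function(x, g, b) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2) + 1e-5)
    g * (x - mu) / s + b
  }
  n <- length(X)
  tok <- vector("list", n + 1)
  tok[[1]] <- p$cls
  for (t in seq_len(n)) {
    proj <- drop(X[[t]] %*% p$W_in) + p$b_in
    tok[[t + 1]] <- ln(proj, p$ln_in_g, p$ln_in_b) +
      if (sc$use_positions) p$pos[t, ] else 0
  }
  lp <- p$layers[[1]]
  l1 <- lapply(tok, ln, g = lp$ln1_g, b = lp$ln1_b)
  Q <- lapply(l1, function(x) drop(x %*% lp$Wq))
  K <- lapply(l1, function(x) drop(x %*% lp$Wk))
  V <- lapply(l1, function(x) drop(x %*% lp$Wv))
  out <- vector("list", n + 1)
  for (t in seq_len(n + 1)) {
    logits <- vapply(K, function(k) sum(Q[[t]] * k) / sqrt(sc$dk),
                     numeric(1))
    a <- exp(logits - max(logits)); a <- a / sum(a)
    o <- Reduce(`+`, Map(function(ai, vi) ai * vi, a, V))
    out[[t]] <- drop(o %*% lp$Wo) + tok[[t]]
  }
  fin <- lapply(out, function(r) {
    h <- pmax(drop(ln(r, lp$ln2_g, lp$ln2_b) %*% lp$W1) + lp$b1, 0)
    drop(h %*% lp$W2) + lp$b2 + r
  })
  sum(fin[[1]] * p$head_w) + p$head_b
}

test_that("the transformer matches a dense single-head oracle", {
  sc <- transformer_scorer(5L, n_tokens = 3L, layers = 1L, heads = 1L,
                           dk = 4L, mlp_hidden = 6L, proj_dim = 8L,
                           seed = 7L)
  set.seed(8)
  X1 <- lapply(1:3, function(t) matrix(rnorm(5), 1, 5))
  expect_equal(transformer_score(sc, X1),
               transformer_oracle_scores(sc, lapply(X1, drop)),
               tolerance = 1e-10)
})

test_that("positional encodings control order sensitivity", {
  mk <- function(pos) {
    transformer_scorer(4L, n_tokens = 3L, layers = 2L, heads = 2L,
                       dk = 3L, mlp_hidden = 6L, proj_dim = 8L,
                       use_positions = pos, seed = 9L)
  }
  set.seed(10)
  X <- lapply(1:3, function(t) matrix(rnorm(3 * 4), 3, 4))
  perm <- c(2, 3, 1)
  no_pos <- mk(FALSE)
  expect_equal(transformer_score(no_pos, X),
               transformer_score(no_pos, X[perm]), tolerance = 1e-12)
  with_pos <- mk(TRUE)
  expect_gt(max(abs(transformer_score(with_pos, X) -
                      transformer_score(with_pos, X[perm]))), 1e-6)
})

test_that("transformer backward agrees with finite differences", {
  sc <- transformer_scorer(4L, n_tokens = 3L, layers = 2L, heads = 2L,
                           dk = 3L, mlp_hidden = 5L, proj_dim = 8L,
                           seed = 11L)
  set.seed(12)
  X <- lapply(1:3, function(t) matrix(rnorm(2 * 4), 2, 4))
  ds <- rnorm(2)
  fwd <- dppa:::transformer_forward(sc, X, keep_cache = TRUE)
  gr <- dppa:::transformer_backward(sc, fwd, ds)
  flat <- unlist(sc$params)
  gflat <- unlist(gr)
  loss <- function(v) {
    s2 <- sc; s2$params <- utils::relist(v, sc$params)
    sum(dppa:::transformer_forward(s2, X)$scores * ds)
  }
  eps <- 1e-6
  set.seed(13)
  for (i in sample(length(flat), 25)) {
    num <- (loss(replace(flat, i, flat[i] + eps)) -
              loss(replace(flat, i, flat[i] - eps))) / (2 * eps)
    expect_equal(gflat[[i]], num, tolerance = 1e-4,
                 label = names(flat)[i])
  }
})

test_that("candidate probabilities are a proper softmax of the scores", {
  pool <- generate_analogy_pool(10L, 40L, seed = 14L)
  cfg <- tiny_config()
  emb <- grid_embedder(cfg)
  sc <- lstm_scorer(cfg$n_frequencies * cfg$n_phases, 8L, seed = 15L)
  cs <- score_problem(pool, sc, emb)
  expect_equal(rowSums(cs$probabilities), rep(1, 40), tolerance = 1e-8)
  expect_true(all(cs$probabilities > 0))
  expect_equal(max.col(cs$probabilities), max.col(cs$scores))
  # zero parameters give equal scores, hence uniform probabilities
  sc0 <- sc
  sc0$params <- lapply(sc0$params, function(p) p * 0)
  cs0 <- score_problem(pool, sc0, emb)
  expect_equal(cs0$probabilities, matrix(1 / 7, 40, 7))
  expect_equal(task_loss(cs0), log(7), tolerance = 1e-12)
})

test_that("the task loss is the negative log probability of the target", {
  s <- matrix(rnorm(21), 3, 7)
  cs <- list(scores = s, target = c(2L, 7L, 1L))
  direct <- -mean(log(t(apply(s, 1, function(r) exp(r) / sum(exp(r))))[
    cbind(1:3, cs$target)]))
  expect_equal(task_loss(cs), direct, tolerance = 1e-12)
  # a dominant target score drives the loss to zero
  s2 <- matrix(0, 1, 7); s2[1, 4] <- 50
  expect_lt(task_loss(list(scores = s2, target = 4L)), 1e-10)
})

test_that("scoring is equivariant under code-preserving translations", {
  # translating all stimuli by a lattice period of the attended frequency
  # leaves its embeddings, hence the probability vector, unchanged
  cfg <- grid_code_config()
  off <- make_offsets(cfg)
  f <- 9L
  delta <- (2 * pi / grid_frequencies(cfg)[f]) * c(1, 1 / sqrt(3))
  pool <- generate_analogy_pool(15L, 30L, seed = 16L)
  sc <- lstm_scorer(cfg$n_phases, 16L, seed = 17L)
  emb0 <- grid_embedder(cfg, off, frequency = f)
  emb1 <- function(points) emb0(sweep(points, 2, delta, "+"))
  cs0 <- score_problem(pool, sc, emb0)
  cs1 <- score_problem(pool, sc, emb1)
  expect_equal(cs1$probabilities, cs0$probabilities, tolerance = 1e-6)
})

test_that("a randomly initialized scorer performs at chance", {
  pool <- generate_analogy_pool(20L, 3000L, seed = 18L)
  cfg <- grid_code_config()
  emb <- grid_embedder(cfg, frequency = 9L)
  sc <- lstm_scorer(cfg$n_phases, 32L, seed = 19L)
  acc <- score_accuracy(score_problem(pool, sc, emb))
  se <- sqrt((1 / 7) * (6 / 7) / 3000)
  expect_lt(abs(acc - 1 / 7), 3 * se)
})
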