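micro_spec <- function(model, ...) {
  desk_analogy_spec(model, seeds = 0L, n_train = 150L, n_eval = 60L,
                    epochs_task = 2L, epochs_dpp = 2L, K_regions = 1L,
                    hidden = 8L, ...)
}

test_that("training reduces the task loss on a small pool", {
  spec <- micro_spec("dppa", epochs_task = 8L, n_train = 300L)
  fit <- dppa:::run_model(spec, 0L)
  k <- length(fit$losses)
  expect_lt(mean(tail(fit$losses, 5)), mean(head(fit$losses, 5)))
  expect_true(all(is.finite(fit$losses)))
})

test_that("the two training phases touch disjoint parameters", {
  spec <- micro_spec("dppa")
  fit <- dppa:::run_model(spec, 0L)
  # gates are reproduced exactly by rerunning phase 1 alone: task training
  # never modified them
  pts <- dppa:::training_region_points(spec$M,
                                       seed = dppa:::derive_seed(0L, 5L))
  cfg <- spec$grid_config
  ker <- build_kernel(encode_batch(pts, cfg, make_offsets(cfg)),
                      wm = spec$wm, b = spec$b)
  gates2 <- optimize_gates(ker, cfg$n_frequencies, cfg$n_phases,
                           epochs = spec$epochs_dpp,
                           batches_per_epoch = spec$batches_per_epoch,
                           lr = spec$lr_dpp, seed = 0L)
  expect_identical(fit$gates$g, gates2$g)
  # scorer parameters did move in phase 2
  init <- lstm_scorer(cfg$n_phases, spec$hidden, seed = 0L)
  expect_false(identical(fit$scorer$params$W, init$params$W))
})

test_that("locked dropout holds one mask across all time steps", {
  fe <- dppa:::new_frontend("dropout", p = 0.5)
  set.seed(31)
  X <- lapply(1:4, function(t) matrix(runif(6 * 10, 1, 2), 6, 10))
  out <- dppa:::frontend_forward(fe, X, train = TRUE)
  ratio1 <- out$Y[[1]] / X[[1]]
  for (t in 2:4) {
    expect_equal(out$Y[[t]] / X[[t]], ratio1, tolerance = 1e-12)
  }
  expect_setequal(unique(as.vector(ratio1)), c(0, 2))
  # evaluation mode is the identity
  expect_identical(dppa:::frontend_forward(fe, X, train = FALSE)$Y, X)
})

test_that("temporal context normalization centers features across time", {
  enc <- dppa:::mlp_encoder(10L, 12L, out_activation = "linear", seed = 32L)
  fe <- dppa:::new_frontend("encoder_tcn", encoder = enc)
  set.seed(33)
  X <- lapply(1:4, function(t) matrix(rnorm(5 * 10), 5, 10))
  out <- dppa:::frontend_forward(fe, X, train = TRUE)
  mu <- Reduce(`+`, out$Y) / 4
  expect_lt(max(abs(mu)), 1e-6)
})

test_that("the L1 gate penalty vanishes at lambda zero", {
  fe0 <- dppa:::new_frontend("gated", input_dim = 6L, l1_lambda = 0)
  feL <- dppa:::new_frontend("gated", input_dim = 6L, l1_lambda = 0.5)
  set.seed(34)
  X <- lapply(1:3, function(t) matrix(rnorm(4 * 6), 4, 6))
  dY <- lapply(1:3, function(t) matrix(rnorm(4 * 6), 4, 6))
  out <- dppa:::frontend_forward(fe0, X)
  g0 <- dppa:::frontend_backward(fe0, out$cache, dY, 4L)$g
  gL <- dppa:::frontend_backward(feL, out$cache, dY, 4L)$g
  # with gates at zero logits the penalty gradient is lambda * 1/4 per gate
  expect_equal(gL - g0, rep(0.5 * 0.25, 6), tolerance = 1e-12)
})

test_that("accuracy equals a direct recount of argmax matches", {
  pool <- generate_analogy_pool(10L, 80L, seed = 35L)
  cfg <- tiny_config()
  emb <- grid_embedder(cfg)
  sc <- lstm_scorer(cfg$n_frequencies * cfg$n_phases, 8L, seed = 36L)
  acc <- evaluate_regions(sc, list(r = pool), emb)
  cs <- score_problem(pool, sc, emb)
  recount <- mean(apply(cs$scores, 1, which.max) == cs$target)
  expect_equal(unname(acc["r"]), recount)
  expect_error(evaluate_regions(sc, list(), emb), "no problem sets")
})

test_that("identical spec and seed reproduce identical fits", {
  spec <- micro_spec("no_dppa")
  f1 <- dppa:::run_model(spec, 1L)
  f2 <- dppa:::run_model(spec, 1L)
  expect_identical(f1$accuracy, f2$accuracy)
  expect_identical(f1$scorer$params, f2$scorer$params)
})

test_that("smoothed one-hot embeddings are normalized and limit to one-hot", {
  pts <- rbind(c(2, 3), c(0, 0), c(4, 1))
  soft <- smoothed_onehot_embedder(5L, sd = 1)(pts)
  expect_equal(rowSums(soft), rep(1, 3))
  tight <- smoothed_onehot_embedder(5L, sd = 1e-6)(pts)
  hard <- onehot_embedder(5L)(pts)
  expect_equal(tight, hard, tolerance = 1e-10)
  expect_equal(rowSums(hard), rep(1, 3))
  expect_equal(hard[1, 2 + 3 * 5 + 1], 1)
})

test_that("the ablation and baseline variants train end to end", {
  for (model in c("locked_dropout", "l1_gates", "tcn")) {
    fit <- dppa:::run_model(micro_spec(model, lambda = 1e-3), 0L)
    expect_true(all(fit$accuracy >= 0 & fit$accuracy <= 1))
    expect_true(all(is.finite(fit$losses)))
  }
  fit <- dppa:::run_model(
    micro_spec("onehot", M = 5L, n_train = 80L, n_eval = 40L,
               dpp_lambda = 0.01, encoder_hidden = 16L), 0L)
  expect_true(all(fit$accuracy >= 0 & fit$accuracy <= 1))
})

test_that("multi-seed aggregation yields bounded accuracies and SEMs", {
  spec <- micro_spec("dppa")
  spec$seeds <- 0:1
  res <- run_experiment(spec)
  expect_s3_class(res, "region_results")
  expect_setequal(res$region, c("train", "val", "K1"))
  expect_true(all(res$mean_acc >= 0 & res$mean_acc <= 1))
  expect_true(all(res$sem >= 0))
  expect_true(all(res$n_seeds == 2))
  csv <- tempfile(fileext = ".csv")
  report_results(res, file = csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(res))
  expect_named(back, c("task", "regime", "model", "scorer", "region",
                       "mean_acc", "sem", "n_seeds"))
})
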