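#' Experiment specification
#'
#' Bundles every setting of one training/evaluation run: the task and its
#' OOD regime, the model variant, the scorer architecture, region and pool
#' sizes, and optimization hyperparameters. Unset hyperparameters resolve
#' to the study defaults: LSTM runs use batch 256, Adam, learning rate
#' 1e-3, and 50 epochs for each phase on analogy problems (500 on
#' arithmetic); transformer runs use batch 128 with learning rate 5e-4 on
#' analogy and 5e-5 on arithmetic.
#'
#' @param task `"analogy"` or `"arithmetic"`.
#' @param regime OOD regime for analogies, `"translate"` or `"scale"`.
#' @param op arithmetic operation, `"add"` or `"multiply"`.
#' @param model one of `"dppa"`, `"no_dppa"`, `"tcn"`, `"locked_dropout"`,
#'   `"l1_gates"`, `"onehot"`, `"smoothed_onehot"`, `"no_attention"`.
#' @param scorer `"lstm"` or `"transformer"`.
#' @param M training region side length.
#' @param n_train problems in the training pool (80/20 train/validation).
#' @param n_eval problems per evaluation region.
#' @param K_regions test region indices to evaluate.
#' @param hidden LSTM hidden units.
#' @param epochs_dpp gate-optimization epochs (NE_DPP).
#' @param epochs_task scorer-training epochs (NE_task).
#' @param batches_per_epoch gate-phase gradient steps per epoch (Nb).
#' @param batch_size task-phase minibatch size (problems).
#' @param lr task-phase learning rate.
#' @param lr_dpp gate-phase learning rate.
#' @param kernel_form attention kernel form, see [build_kernel()].
#' @param wm,b kernel hyperparameters.
#' @param dropout_p locked dropout rate.
#' @param lambda L1 penalty strength(s) for `l1_gates`; a vector is swept
#'   with the best validation accuracy reported.
#' @param dpp_lambda combined-loss weight(s) for the ablation models.
#' @param embedding ablation embedding: `"grid"`, `"onehot"`, or
#'   `"smoothed_onehot"` (only used by `no_attention`).
#' @param sd smoothing of the smoothed one-hot embedding.
#' @param encoder_hidden feedforward encoder width (256 for the TCN
#'   baseline, 1024 for the ablation encoder).
#' @param seeds integer vector of run seeds.
#' @param grid_config grid-code configuration, see [grid_code_config()].
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(task = c("analogy", "arithmetic"),
                            regime = c("translate", "scale"),
                            op = c("add", "multiply"),
                            model = "dppa",
                            scorer = c("lstm", "transformer"),
                            M = 100L,
                            n_train = 10000L,
                            n_eval = 2000L,
                            K_regions = 1:9,
                            hidden = 512L,
                            epochs_dpp = NULL,
                            epochs_task = NULL,
                            batches_per_epoch = 1L,
                            batch_size = NULL,
                            lr = NULL,
                            lr_dpp = 1e-3,
                            kernel_form = "quality_diversity",
                            wm = 1, b = 0.1,
                            dropout_p = 0.5,
                            lambda = c(1e-4, 1e-3, 1e-2),
                            dpp_lambda = c(0.001, 0.01, 0.1, 1, 10, 100,
                                           1000, 10000),
                            embedding = "grid",
                            sd = 1,
                            encoder_hidden = NULL,
                            seeds = 0:2,
                            grid_config = grid_code_config()) {
  task <- match.arg(task)
  regime <- match.arg(regime)
  op <- match.arg(op)
  scorer <- match.arg(scorer)
  models <- c("dppa", "no_dppa", "tcn", "locked_dropout", "l1_gates",
              "onehot", "smoothed_onehot", "no_attention")
  model <- match.arg(model, models)
  default_epochs <- if (task == "analogy") 50L else 500L
  if (is.null(epochs_dpp)) epochs_dpp <- default_epochs
  if (is.null(epochs_task)) epochs_task <- default_epochs
  if (is.null(batch_size)) batch_size <- if (scorer == "lstm") 256L else 128L
  if (is.null(lr)) {
    lr <- if (scorer == "lstm") 1e-3 else if (task == "analogy") 5e-4 else 5e-5
  }
  if (is.null(encoder_hidden)) {
    encoder_hidden <- if (model == "tcn") 256L else 1024L
  }
  if (model %in% c("onehot", "smoothed_onehot")) {
    embedding <- if (model == "onehot") "onehot" else "smoothed_onehot"
  }
  structure(
    list(task = task, regime = regime, op = op, model = model,
         scorer = scorer, M = as.integer(M), n_train = as.integer(n_train),
         n_eval = as.integer(n_eval), K_regions = as.integer(K_regions),
         hidden = as.integer(hidden), epochs_dpp = as.integer(epochs_dpp),
         epochs_task = as.integer(epochs_task),
         batches_per_epoch = as.integer(batches_per_epoch),
         batch_size = as.integer(batch_size), lr = lr, lr_dpp = lr_dpp,
         kernel_form = kernel_form, wm = wm, b = b, dropout_p = dropout_p,
         lambda = lambda, dpp_lambda = dpp_lambda, embedding = embedding,
         sd = sd, encoder_hidden = as.integer(encoder_hidden),
         seeds = as.integer(seeds), grid_config = grid_config),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf(
    "experiment: %s (%s), model %s, scorer %s, M = %d, regions K = %s\n",
    x$task, if (x$task == "analogy") x$regime else x$op, x$model, x$scorer,
    x$M, paste(range(x$K_regions), collapse = "..")
  ))
  invisible(x)
}

#' Desk-scale presets
#'
#' Reduced configurations sized so that a full two-model comparison runs on
#' a single CPU core in minutes: a 20 x 20 training region, three test
#' regions, a 3000-problem training pool, 2000-problem evaluation sets, a
#' 64-unit LSTM, 20 gate-optimization epochs, and 30 task epochs at
#' learning rate 2e-3 (the slightly higher rate compensates for the reduced
#' epoch count). The grid-code configuration itself is unchanged
#' (9 frequencies x 100 phases).
#'
#' @param model model variant, as in [experiment_spec()].
#' @param ... overrides passed to [experiment_spec()].
#' @return an `experiment_spec`.
#' @export
desk_analogy_spec <- function(model = "dppa", ...) {
  args <- list(task = "analogy", model = model, M = 20L, n_train = 3000L,
               n_eval = 2000L, K_regions = 1:3, hidden = 64L,
               epochs_dpp = 20L, epochs_task = 30L, batch_size = 128L,
               batches_per_epoch = 5L, lr = 2e-3)
  override <- list(...)
  args[names(override)] <- override
  do.call(experiment_spec, args)
}

#' @rdname desk_analogy_spec
#' @export
desk_arithmetic_spec <- function(model = "dppa", ...) {
  args <- list(task = "arithmetic", model = model, M = 20L, n_train = 3000L,
               n_eval = 2000L, K_regions = 1:3, hidden = 64L,
               epochs_dpp = 20L, epochs_task = 30L, batch_size = 128L,
               batches_per_epoch = 5L, lr = 2e-3)
  override <- list(...)
  args[names(override)] <- override
  do.call(experiment_spec, args)
}

## Uniform sample of the continuous training region [0, M-1]^2 for kernel
## statistics. The attention kernel estimates second-order statistics of
## the code over the training region; sampling only the integer stimulus
## lattice would alias spatial frequencies above the lattice Nyquist limit
## (the default top frequency, 0.72 cycles/unit, exceeds 0.5) and so
## misstate the top block's correlations.
training_region_points <- function(M, n_points = 2048L, seed = 0L) {
  with_seed(seed, cbind(stats::runif(n_points, 0, M - 1),
                        stats::runif(n_points, 0, M - 1)))
}

## Embedding function + dimension for a spec (before the op one-hot).
spec_embedder <- function(spec, frequency = NULL) {
  if (spec$embedding == "grid" ||
      !(spec$model %in% c("onehot", "smoothed_onehot", "no_attention"))) {
    cfg <- spec$grid_config
    off <- make_offsets(cfg)
    fn <- grid_embedder(cfg, off, frequency)
    dim <- if (is.null(frequency)) cfg$n_frequencies * cfg$n_phases else cfg$n_phases
  } else {
    mult <- if (spec$task == "analogy" && spec$regime == "scale") {
      max(spec$K_regions)
    } else {
      max(spec$K_regions) + 1L
    }
    extent <- mult * spec$M
    fn <- if (spec$embedding == "onehot") {
      onehot_embedder(extent)
    } else {
      smoothed_onehot_embedder(extent, spec$sd)
    }
    dim <- extent^2
  }
  list(fn = fn, dim = dim)
}

make_training_pool <- function(spec, seed) {
  if (spec$task == "analogy") {
    generate_analogy_pool(spec$M, spec$n_train, derive_seed(seed, 11L))
  } else {
    generate_arithmetic(spec$M, spec$op, 0L, spec$n_train,
                        derive_seed(seed, 11L))
  }
}

make_eval_sets <- function(spec, seed) {
  pool <- make_training_pool(spec, seed)
  cap <- function(ps) {
    if (ps$n > spec$n_eval) subset_problems(ps, seq_len(spec$n_eval)) else ps
  }
  sets <- list(
    train = cap(subset_problems(pool, "train")),
    val = subset_problems(pool, "val")
  )
  if (spec$task == "analogy") {
    eval_pool <- generate_analogy_pool(spec$M, spec$n_eval,
                                       derive_seed(seed, 777L))
    for (K in spec$K_regions) {
      sets[[paste0("K", K)]] <- if (spec$regime == "translate") {
        translate_problems(eval_pool, K)
      } else {
        scale_problems(eval_pool, K)
      }
    }
  } else {
    for (K in spec$K_regions) {
      sets[[paste0("K", K)]] <- generate_arithmetic(
        spec$M, spec$op, K, spec$n_eval, derive_seed(seed, 777L + K)
      )
    }
  }
  sets
}

## Fit one model under one seed. Returns the trained scorer, any frontend,
## DPP artifacts for the dppa model, and per-region accuracies.
run_model <- function(spec, seed = 0L) {
  emb <- spec_embedder(spec)
  gates <- NULL
  fscore <- NULL
  kernel <- NULL
  if (spec$model == "dppa") {
    cfg <- spec$grid_config
    pts <- training_region_points(spec$M, seed = derive_seed(seed, 5L))
    kernel <- build_kernel(emb$fn(pts), wm = spec$wm, b = spec$b,
                           form = spec$kernel_form)
    gates <- optimize_gates(kernel, cfg$n_frequencies, cfg$n_phases,
                            epochs = spec$epochs_dpp,
                            batches_per_epoch = spec$batches_per_epoch,
                            lr = spec$lr_dpp, seed = seed)
    fscore <- select_max_frequency(gates, kernel, cfg$n_frequencies,
                                   cfg$n_phases)
    emb <- spec_embedder(spec, frequency = fscore$f_max)
  }
  input_dim <- emb$dim + if (spec$task == "arithmetic") 2L else 0L

  pool <- make_training_pool(spec, seed)
  train_ps <- subset_problems(pool, "train")
  val_ps <- subset_problems(pool, "val")
  seqs <- build_sequences(train_ps, emb$fn)

  scorer_dim <- if (spec$model == "tcn") spec$encoder_hidden else
    if (spec$model %in% c("onehot", "smoothed_onehot")) spec$encoder_hidden else
      input_dim
  make_scorer <- function(s) {
    if (spec$scorer == "lstm") {
      lstm_scorer(scorer_dim, spec$hidden, seed = s)
    } else {
      transformer_scorer(scorer_dim,
                         n_tokens = if (spec$task == "analogy") 4L else 3L,
                         seed = s)
    }
  }
  make_frontend <- function(lam) {
    switch(spec$model,
      dppa = new_frontend("plain"),
      no_dppa = new_frontend("plain"),
      no_attention = new_frontend("plain"),
      locked_dropout = new_frontend("dropout", p = spec$dropout_p),
      l1_gates = new_frontend("gated", input_dim = input_dim,
                              l1_lambda = lam),
      tcn = new_frontend("encoder_tcn", encoder = mlp_encoder(
        input_dim, spec$encoder_hidden, out_activation = "linear",
        seed = derive_seed(seed, 77L)
      )),
      new_frontend("encoder_gated",
                   encoder = mlp_encoder(
                     input_dim, spec$encoder_hidden,
                     out_activation = "sigmoid",
                     seed = derive_seed(seed, 77L)
                   ),
                   dpp_lambda = lam, wm = spec$wm, b = spec$b,
                   kernel_inputs = {
                     kp <- floor(training_region_points(
                       spec$M, 512L, seed = derive_seed(seed, 5L)
                     ))
                     ki <- emb$fn(kp)
                     if (spec$task == "arithmetic") {
                       ki <- cbind(ki, matrix(op_onehot(spec$op),
                                              nrow(ki), 2L, byrow = TRUE))
                     }
                     ki
                   })
    )
  }

  sweep_values <- if (spec$model == "l1_gates") {
    spec$lambda
  } else if (spec$model %in% c("onehot", "smoothed_onehot")) {
    spec$dpp_lambda
  } else {
    NA_real_
  }

  best <- NULL
  for (lam in sweep_values) {
    fit <- train_scorer_engine(
      make_scorer(seed), seqs,
      epochs = spec$epochs_task, batch_size = spec$batch_size,
      lr = spec$lr, seed = seed, frontend = make_frontend(lam)
    )
    val_acc <- evaluate_regions(fit$scorer, list(val = val_ps), emb$fn,
                                frontend = fit$frontend)[["val"]]
    if (is.null(best) || val_acc > best$val_acc) {
      best <- list(fit = fit, val_acc = val_acc, lambda = lam)
    }
  }

  sets <- make_eval_sets(spec, seed)
  acc <- evaluate_regions(best$fit$scorer, sets, emb$fn,
                          frontend = best$fit$frontend)
  list(
    scorer = best$fit$scorer, frontend = best$fit$frontend,
    gates = gates, frequency_score = fscore, kernel = kernel,
    f_max = if (is.null(fscore)) NA_integer_ else fscore$f_max,
    lambda = best$lambda, losses = best$fit$losses,
    accuracy = acc, seed = seed
  )
}

#' Two-phase training with DPP attention
#'
#' Phase 1 builds the attention kernel from grid-code activations over the
#' training region and optimizes the gates under the DPP objective; the
#' frequency with the maximal within-frequency log-determinant is selected.
#' Phase 2 trains the scorer on embeddings restricted to that frequency by
#' minimizing the candidate cross-entropy. Gates move only in phase 1 and
#' scorer parameters only in phase 2; the gates are never modified during
#' or after task training.
#'
#' @param spec an [experiment_spec()] with `model = "dppa"`.
#' @param seed run seed.
#' @return list with the trained `scorer`, the optimized `gates`, the
#'   per-frequency `frequency_score` (including `f_max`), the `kernel`, and
#'   per-region `accuracy`.
#' @export
train_dppa <- function(spec, seed = 0L) {
  if (spec$model != "dppa") stop("spec$model must be 'dppa'")
  run_model(spec, seed)
}

#' Train a comparison model
#'
#' Baselines sharing the grid-code input: the full 900-cell code with no
#' attention (`no_dppa`), a feedforward encoder with temporal context
#' normalization (`tcn`), locked dropout over grid cells
#' (`locked_dropout`), and jointly trained gates with an L1 penalty on the
#' gate activations (`l1_gates`; the `lambda` grid is swept and the best
#' validation accuracy reported).
#'
#' @param spec an [experiment_spec()] with a baseline `model`.
#' @param seed run seed.
#' @return as [train_dppa()], without DPP artifacts.
#' @export
train_baseline <- function(spec, seed = 0L) {
  if (!spec$model %in% c("no_dppa", "tcn", "locked_dropout", "l1_gates")) {
    stop("spec$model must be a baseline model")
  }
  run_model(spec, seed)
}

#' Train an ablation model
#'
#' Replaces the grid code with one-hot or smoothed one-hot ("place cell")
#' embeddings passed through a learned feedforward encoder. Because these
#' embeddings have no frequency structure, gate optimization cannot be a
#' separate phase; gates, encoder and scorer are trained jointly with the
#' combined loss `L = L_task - lambda * Fhat(g, V)` over the `dpp_lambda`
#' grid, reporting the best validation accuracy. `no_attention` runs the
#' configured embedding straight into the scorer with no attention or
#' regularization.
#'
#' @param spec an [experiment_spec()] with an ablation `model`.
#' @param seed run seed.
#' @return as [train_dppa()].
#' @export
train_ablation <- function(spec, seed = 0L) {
  if (!spec$model %in% c("onehot", "smoothed_onehot", "no_attention")) {
    stop("spec$model must be an ablation model")
  }
  run_model(spec, seed)
}

#' Run an experiment over its seeds
#'
#' Fits the spec's model once per seed and aggregates per-region accuracy
#' into mean and standard error of the mean.
#'
#' @param spec an [experiment_spec()].
#' @param keep_fits retain the per-seed fit objects.
#' @return object of class `region_results`: a data frame with columns
#'   task, regime, model, scorer, region, mean_acc, sem, n_seeds (and the
#'   per-seed fits in `attr(, "fits")` if requested).
#' @export
run_experiment <- function(spec, keep_fits = FALSE) {
  fits <- lapply(spec$seeds, function(s) run_model(spec, s))
  acc <- do.call(rbind, lapply(fits, `[[`, "accuracy"))
  ns <- nrow(acc)
  sem <- if (ns > 1) apply(acc, 2L, stats::sd) / sqrt(ns) else rep(0, ncol(acc))
  res <- data.frame(
    task = spec$task,
    regime = if (spec$task == "analogy") spec$regime else spec$op,
    model = spec$model,
    scorer = spec$scorer,
    region = colnames(acc),
    mean_acc = colMeans(acc),
    sem = sem,
    n_seeds = ns,
    row.names = NULL
  )
  class(res) <- c("region_results", class(res))
  if (keep_fits) attr(res, "fits") <- fits
  res
}

#' Write and plot region results
#'
#' `report_results()` writes the per-region accuracy table of one or more
#' [run_experiment()] results to a CSV file (columns task, regime, model,
#' scorer, region, mean_acc, sem, n_seeds). `plot_region_results()` draws
#' accuracy against region (train, val, K1, K2, ...) with one line per
#' model and SEM error bars.
#'
#' @param ... `region_results` objects.
#' @param file output CSV path.
#' @return the combined data frame, invisibly.
#' @export
report_results <- function(..., file) {
  combined <- do.call(rbind, lapply(list(...), as.data.frame))
  utils::write.csv(combined, file, row.names = FALSE)
  invisible(combined)
}

#' @rdname report_results
#' @param results a `region_results` data frame (possibly combined).
#' @param main plot title.
#' @export
plot_region_results <- function(results, main = "OOD generalization") {
  results <- as.data.frame(results)
  regions <- unique(results$region)
  ord <- order(match(regions, c("train", "val",
                                paste0("K", 1:99))))
  regions <- regions[ord]
  models <- unique(results$model)
  cols <- grDevices::hcl.colors(max(3L, length(models)), "Dark 3")
  graphics::plot(NULL, xlim = c(1, length(regions)), ylim = c(0, 1),
                 xaxt = "n", xlab = "region", ylab = "accuracy",
                 main = main)
  graphics::axis(1, at = seq_along(regions), labels = regions)
  graphics::abline(h = 1 / 7, lty = 3, col = "grey50")
  for (i in seq_along(models)) {
    sub <- results[results$model == models[i], ]
    y <- sub$mean_acc[match(regions, sub$region)]
    s <- sub$sem[match(regions, sub$region)]
    graphics::lines(seq_along(regions), y, col = cols[i], type = "b",
                    pch = 16)
    graphics::arrows(seq_along(regions), y - s, seq_along(regions), y + s,
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("bottomleft", legend = models, col = cols[seq_along(models)],
                   lty = 1, pch = 16, bty = "n")
  invisible(results)
}
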