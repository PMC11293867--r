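## Problem scoring: build per-candidate stimulus sequences, score them with
## an inference module (LSTM or transformer), and normalize the seven
## candidate scores with a softmax.

scorer_forward <- function(scorer, X, keep_cache = FALSE) {
  if (inherits(scorer, "lstm_scorer")) {
    lstm_forward(scorer, X, keep_cache)
  } else {
    transformer_forward(scorer, X, keep_cache)
  }
}

scorer_backward <- function(scorer, X, fwd, dscores, want_dx = FALSE) {
  if (inherits(scorer, "lstm_scorer")) {
    lstm_backward(scorer, X, fwd, dscores, want_dx)
  } else {
    grads <- transformer_backward(scorer, fwd, dscores, want_dx)
    dX <- attr(grads, "dX")
    attr(grads, "dX") <- NULL
    list(grads = grads, dX = dX)
  }
}

scorer_params <- function(scorer) scorer$params

set_scorer_params <- function(scorer, params) {
  scorer$params <- params
  scorer
}

#' Grid-code embedding function
#'
#' Returns a function mapping an n x 2 matrix of integer locations to their
#' grid-cell embeddings, optionally restricted to a single frequency block
#' (the DPP-attended pathway).
#'
#' @param config a [grid_code_config()].
#' @param offsets offset table from [make_offsets()]; built from `config`
#'   if omitted.
#' @param frequency if non-`NULL`, restrict embeddings to this frequency's
#'   `n_phases` cells.
#' @return function(points) -> numeric matrix.
#' @export
grid_embedder <- function(config, offsets = make_offsets(config),
                          frequency = NULL) {
  force(config); force(offsets); force(frequency)
  function(points) {
    emb <- encode_batch(points, config, offsets)
    if (!is.null(frequency)) {
      emb <- restrict_to_frequency(emb, frequency, config$n_phases)
    }
    emb
  }
}

op_onehot <- function(op) {
  if (identical(op, "add")) c(1, 0) else c(0, 1)
}

#' Build per-candidate stimulus sequences for a problem set
#'
#' Each of the n x 7 candidate evaluations becomes one sequence: the
#' stimulus embeddings (A, B, C for analogies; A, B for arithmetic) followed
#' by the candidate's embedding. For arithmetic, a 2-dimensional one-hot
#' flag for the operation is appended to every vector. Rows are ordered
#' problem-major: sequence (i - 1) * 7 + k is problem i, candidate k.
#'
#' @param ps a `problem_set`.
#' @param embed_fn embedding function (points matrix -> embedding matrix),
#'   e.g. from [grid_embedder()].
#' @return list with `X` (list of T matrices, each (n * 7) x input_dim),
#'   `target` (length-n vector of correct candidate positions), `n`, and
#'   `input_dim`.
#' @export
build_sequences <- function(ps, embed_fn) {
  cand <- assemble_candidates(ps)
  n <- ps$n
  stim_names <- if (ps$task == "analogy") c("A", "B", "C") else c("A", "B")
  rep_idx <- rep(seq_len(n), each = 7L)
  X <- vector("list", length(stim_names) + 1L)
  for (s in seq_along(stim_names)) {
    emb <- embed_fn(ps$points[[stim_names[s]]])
    X[[s]] <- emb[rep_idx, , drop = FALSE]
  }
  cand_pts <- cbind(as.vector(t(cand$candidates[, , 1L])),
                    as.vector(t(cand$candidates[, , 2L])))
  X[[length(X)]] <- embed_fn(cand_pts)
  if (ps$task == "arithmetic") {
    oh <- op_onehot(ps$op)
    X <- lapply(X, function(m) {
      cbind(m, matrix(oh, nrow(m), 2L, byrow = TRUE))
    })
  }
  list(X = X, target = cand$target, n = n, input_dim = ncol(X[[1]]))
}

#' Score every candidate of every problem
#'
#' Embeds the stimuli and candidates, scores each of the seven
#' candidate-completed sequences independently, and softmax-normalizes the
#' scores within each problem.
#'
#' @param ps a `problem_set`.
#' @param scorer an [lstm_scorer()] or [transformer_scorer()].
#' @param embed_fn embedding function, e.g. from [grid_embedder()].
#' @return object of class `candidate_scores`: list with `scores` and
#'   `probabilities` (n x 7 matrices) and `target` (length-n vector).
#' @export
score_problem <- function(ps, scorer, embed_fn) {
  seqs <- build_sequences(ps, embed_fn)
  raw <- scorer_forward(scorer, seqs$X)$scores
  scores <- matrix(raw, seqs$n, 7L, byrow = TRUE)
  structure(
    list(scores = scores, probabilities = softmax(scores),
         target = seqs$target),
    class = "candidate_scores"
  )
}

#' Cross-entropy task loss
#'
#' Mean over problems of `-log(softmax(scores)[target])`, the negative log
#' probability assigned to the correct completion.
#'
#' @param scores a `candidate_scores` object from [score_problem()], or a
#'   list with `scores` (n x 7) and `target`.
#' @return scalar loss in nats.
#' @export
task_loss <- function(scores) {
  s <- scores$scores
  tg <- scores$target
  # log-sum-exp per row for stability
  mx <- apply(s, 1L, max)
  lse <- mx + log(rowSums(exp(s - mx)))
  picked <- s[cbind(seq_len(nrow(s)), tg)]
  mean(lse - picked)
}

#' Accuracy of candidate scores
#'
#' Fraction of problems whose highest-probability candidate is the correct
#' completion.
#'
#' @param scores a `candidate_scores` object.
#' @return scalar in `[0, 1]`.
#' @export
score_accuracy <- function(scores) {
  mean(max.col(scores$scores, ties.method = "first") == scores$target)
}
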