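## Multiple-choice analogy and arithmetic problem generators.
##
## Problems live on 2D integer grids. Training problems occupy [0, M-1]^2;
## out-of-distribution test problems are produced either by translating all
## constituents by K*M along both axes (region [KM, (K+1)M-1]^2) or by
## scaling them by K (region [0, KM-1]^2). Every problem carries one correct
## completion and six foils from the same region, so chance performance is
## 1/7.

new_problem_set <- function(task, points, foils, op = NULL, split,
                            M, regime, K, seed) {
  structure(
    list(task = task, points = points, foils = foils, op = op,
         split = split, M = M, regime = regime, K = K, seed = seed,
         n = nrow(points[[1]])),
    class = "problem_set"
  )
}

#' @export
print.problem_set <- function(x, ...) {
  cat(sprintf(
    "%s problem set: %d problems, M = %d, regime = %s, K = %d\n",
    x$task, x$n, x$M, x$regime, x$K
  ))
  if (!is.null(x$op)) cat(sprintf("  op: %s\n", x$op))
  cat(sprintf("  split: %s\n",
              paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Correct completion of each problem
#'
#' @param ps a `problem_set`.
#' @return n x 2 integer matrix (D for analogies, C for arithmetic).
#' @export
problem_answers <- function(ps) {
  if (ps$task == "analogy") ps$points$D else ps$points$C
}

region_bounds <- function(regime, K, M) {
  if (regime == "scale") {
    c(lo = 0L, hi = as.integer(max(K, 1L) * M - 1L))
  } else {
    c(lo = as.integer(K * M), hi = as.integer((K + 1L) * M - 1L))
  }
}

## Uniform sample of `k` distinct points from the square [lo, hi]^2
## excluding `exclude` (a 2-vector). Returns a k x 2 integer matrix.
sample_foils <- function(k, lo, hi, exclude) {
  side <- hi - lo + 1L
  ncell <- as.numeric(side)^2
  if (ncell < k + 1) stop("region too small to sample foils")
  excl_idx <- (exclude[1] - lo) * side + (exclude[2] - lo) # 0-based
  idx <- sample(ncell - 1, k) - 1
  idx <- ifelse(idx >= excl_idx, idx + 1, idx)
  cbind(as.integer(lo + idx %/% side), as.integer(lo + idx %% side))
}

resample_all_foils <- function(n, lo, hi, answers, seed) {
  with_seed(seed, {
    foils <- array(0L, dim = c(n, 6L, 2L))
    for (i in seq_len(n)) {
      foils[i, , ] <- sample_foils(6L, lo, hi, answers[i, ])
    }
    foils
  })
}

make_split <- function(n, seed) {
  n_val <- round(0.2 * n)
  split <- rep("train", n)
  split[with_seed(derive_seed(seed, 999983L), sample.int(n, n_val))] <- "val"
  split
}

#' Generate a pool of training analogies
#'
#' Samples proportional analogies A:B::C:D on the integer square
#' `[0, M-1]^2`: A and B are drawn uniformly (equivalently, A uniform and
#' the displacement v = B - A uniform over displacements feasible at A),
#' then C is drawn uniformly among positions for which C + v stays inside
#' the region, and D = C + v, so the parallelogram identity B - A = D - C
#' holds by construction. Each problem receives six foils drawn uniformly
#' without replacement from the region excluding D. Problems are split 80/20
#' into train and validation.
#'
#' @param M side length of the training region (>= 3 so the region can hold
#'   seven distinct candidates).
#' @param n number of problems.
#' @param seed integer seed; the same seed reproduces the set exactly.
#' @return a `problem_set` with points A, B, C, D, foils, and split labels.
#' @export
generate_analogy_pool <- function(M, n = 1000L, seed = 0L) {
  M <- as.integer(M)
  if (M * M < 7L) stop("M too small: region must contain at least 7 points")
  n <- as.integer(n)
  pts <- with_seed(seed, {
    A <- cbind(sample.int(M, n, replace = TRUE) - 1L,
               sample.int(M, n, replace = TRUE) - 1L)
    B <- cbind(sample.int(M, n, replace = TRUE) - 1L,
               sample.int(M, n, replace = TRUE) - 1L)
    v <- B - A
    # C uniform over positions keeping C + v inside [0, M-1]^2
    clo <- pmax(-v, 0L)
    chi <- pmin(M - 1L - v, M - 1L)
    C <- clo + cbind(
      as.integer(floor(stats::runif(n) * (chi[, 1] - clo[, 1] + 1L))),
      as.integer(floor(stats::runif(n) * (chi[, 2] - clo[, 2] + 1L)))
    )
    D <- C + v
    foils <- array(0L, dim = c(n, 6L, 2L))
    for (i in seq_len(n)) {
      foils[i, , ] <- sample_foils(6L, 0L, M - 1L, D[i, ])
    }
    list(A = A, B = B, C = C, D = D, foils = foils)
  })
  new_problem_set(
    task = "analogy",
    points = pts[c("A", "B", "C", "D")],
    foils = pts$foils,
    split = make_split(n, seed),
    M = M, regime = "train", K = 0L, seed = seed
  )
}

#' Translate analogies into a remote test region
#'
#' Adds K*M to both coordinates of every constituent, so a training analogy
#' A:B::C:D becomes A+KM : B+KM :: C+KM : D+KM inside
#' `[KM, (K+1)M-1]^2`. Foils are re-sampled from the translated region
#' (excluding the translated D); reusing training-range foils would let a
#' scorer solve the task by range detection alone.
#'
#' @param pool a training `problem_set` from [generate_analogy_pool()].
#' @param K integer region index (0 leaves the pool unchanged).
#' @param M training region size (defaults to the pool's).
#' @return a test `problem_set`.
#' @export
translate_problems <- function(pool, K, M = pool$M) {
  K <- as.integer(K)
  if (K == 0L) return(pool)
  shift <- K * as.integer(M)
  pts <- lapply(pool$points, function(p) p + shift)
  bounds <- region_bounds("translate", K, M)
  foils <- resample_all_foils(pool$n, bounds["lo"], bounds["hi"],
                              pts$D, derive_seed(pool$seed, 100L + K))
  new_problem_set("analogy", pts, foils,
                  split = rep("test", pool$n),
                  M = pool$M, regime = "translate", K = K, seed = pool$seed)
}

#' Scale analogies into an enlarged test region
#'
#' Multiplies every constituent by K, so A:B::C:D becomes KA:KB::KC:KD
#' inside `[0, KM-1]^2`. Foils are re-sampled from the scaled region
#' excluding KD.
#'
#' @inheritParams translate_problems
#' @export
scale_problems <- function(pool, K, M = pool$M) {
  K <- as.integer(K)
  pts <- lapply(pool$points, function(p) p * K)
  if (K == 1L) {
    foils <- pool$foils
  } else {
    bounds <- region_bounds("scale", K, M)
    foils <- resample_all_foils(pool$n, bounds["lo"], bounds["hi"],
                                pts$D, derive_seed(pool$seed, 200L + K))
  }
  new_problem_set("analogy", pts, foils,
                  split = rep("test", pool$n),
                  M = pool$M, regime = "scale", K = K, seed = pool$seed)
}

## Uniform draw over ordered divisor pairs (a, b) with a * b = c (c >= 1).
sample_divisor_pair <- function(c, M) {
  if (c == 0L) {
    return(c(0L, sample.int(M, 1L) - 1L))
  }
  d <- which(c %% seq_len(c) == 0L)
  a <- d[sample.int(length(d), 1L)]
  c(as.integer(a), as.integer(c %/% a))
}

#' Generate arithmetic problems
#'
#' Elementwise addition or multiplication problems A o B = C on 2D integer
#' points. The answer C is sampled uniformly from the target region
#' (`[0, M-1]^2` for K = 0, the training region, else `[KM, (K+1)M-1]^2`),
#' then factored: for addition each coordinate A_d is uniform on
#' `[0, C_d]` with B_d = C_d - A_d; for multiplication (A_d, B_d) is drawn
#' uniformly over ordered divisor pairs of C_d (C_d = 0 yields A_d = 0 and
#' B_d uniform on `[0, M-1]`). Six foils come from the same region as C.
#' K = 0 sets are split 80/20 train/validation; K >= 1 sets are test-only.
#'
#' @param M training region size.
#' @param op `"add"` or `"multiply"`.
#' @param K region index in `[0, 9]` (0 = training region).
#' @param n number of problems.
#' @param seed integer seed.
#' @return a `problem_set` with points A, B, C, an `op` flag, and foils.
#' @export
generate_arithmetic <- function(M, op = c("add", "multiply"), K = 0L,
                                n = 1000L, seed = 0L) {
  op <- match.arg(op)
  M <- as.integer(M)
  K <- as.integer(K)
  n <- as.integer(n)
  if (M * M < 7L) stop("M too small: region must contain at least 7 points")
  bounds <- region_bounds("translate", K, M)
  lo <- bounds["lo"]; hi <- bounds["hi"]
  out <- with_seed(seed, {
    C <- cbind(lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L,
               lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
    A <- matrix(0L, n, 2L)
    B <- matrix(0L, n, 2L)
    for (i in seq_len(n)) {
      for (d in 1:2) {
        if (op == "add") {
          A[i, d] <- sample.int(C[i, d] + 1L, 1L) - 1L
          B[i, d] <- C[i, d] - A[i, d]
        } else {
          ab <- sample_divisor_pair(C[i, d], M)
          A[i, d] <- ab[1]
          B[i, d] <- ab[2]
        }
      }
    }
    foils <- array(0L, dim = c(n, 6L, 2L))
    for (i in seq_len(n)) {
      foils[i, , ] <- sample_foils(6L, lo, hi, C[i, ])
    }
    list(A = A, B = B, C = C, foils = foils)
  })
  split <- if (K == 0L) make_split(n, seed) else rep("test", n)
  new_problem_set("arithmetic", out[c("A", "B", "C")], out$foils, op = op,
                  split = split, M = M,
                  regime = if (K == 0L) "train" else "translate",
                  K = K, seed = seed)
}

#' Assemble shuffled candidate lists
#'
#' Places each problem's correct completion among its six foils in a random
#' order, using a per-problem seed derived from the set's seed and the
#' problem index, and records where the correct completion landed.
#'
#' @param ps a `problem_set`.
#' @return list with `candidates` (n x 7 x 2 integer array) and `target`
#'   (integer vector in `[1, 7]`, the correct completion's position).
#' @export
assemble_candidates <- function(ps) {
  ans <- problem_answers(ps)
  n <- ps$n
  candidates <- array(0L, dim = c(n, 7L, 2L))
  target <- integer(n)
  base <- derive_seed(ps$seed, 300L + ps$K +
                        10L * (ps$regime == "scale") +
                        20L * identical(ps$op, "multiply"))
  orig <- if (is.null(ps$index)) seq_len(n) else ps$index
  for (i in seq_len(n)) {
    pool7 <- rbind(ans[i, ], ps$foils[i, , ])
    perm <- with_seed(derive_seed(base, orig[i]), sample.int(7L))
    candidates[i, , ] <- pool7[perm, ]
    target[i] <- which(perm == 1L)
  }
  list(candidates = candidates, target = target)
}

#' Select a subset of problems
#'
#' @param ps a `problem_set`.
#' @param idx integer indices or a split label (`"train"`, `"val"`,
#'   `"test"`).
#' @return a `problem_set` containing the selected problems.
#' @export
subset_problems <- function(ps, idx) {
  if (is.character(idx)) idx <- which(ps$split == idx)
  ps2 <- ps
  ps2$points <- lapply(ps$points, function(p) p[idx, , drop = FALSE])
  ps2$foils <- ps$foils[idx, , , drop = FALSE]
  ps2$split <- ps$split[idx]
  ps2$n <- length(idx)
  ps2$index <- if (is.null(ps$index)) idx else ps$index[idx]
  ps2
}
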