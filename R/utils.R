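#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix (or to a single
#' vector).
#'
#' @param x numeric matrix (rows are normalized independently) or vector.
#' @return object of the same shape with non-negative entries; rows sum to 1.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    z <- x - max(x)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- x - apply(x, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Deterministic per-item seed derived from a run seed; kept below 2^31 so it
## is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, label = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", label), call. = FALSE)
  }
  invisible(x)
}
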