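#' Grid-cell encoder configuration
#'
#' The encoder represents a 2D location as the firing rates of a population
#' of idealized grid cells. Cells are organized into `n_frequencies` discrete
#' spatial frequencies; frequency f responds with spatial frequency
#' `base_frequency * frequency_ratio^(f-1)` (radians per unit length). Each
#' frequency contains `n_phases` cells that differ only in their phase
#' offset, laid out to tile the periodic phase space evenly.
#'
#' Defaults follow empirical estimates for entorhinal grid modules: nine
#' geometrically spaced frequencies (ratio 2) starting at 0.0028 * 2 * pi
#' radians per unit, with 100 phases per frequency, giving a 900-cell code
#' intended to cover a 1000 x 1000 integer space. `space_extent` is
#' documentation of that intended coverage only; the encoder itself is
#' defined for any finite location.
#'
#' @param n_frequencies number of discrete spatial frequencies (Nf).
#' @param n_phases number of phase offsets per frequency (Np); must be a
#'   perfect square for the regular offset lattice.
#' @param base_frequency lowest spatial frequency, radians per unit length.
#' @param frequency_ratio geometric ratio between successive frequencies
#'   (must exceed 1).
#' @param space_extent side length of the integer space the code is intended
#'   to cover (metadata only).
#' @return object of class `grid_code_config`.
#' @examples
#' cfg <- grid_code_config()
#' grid_frequencies(cfg)
#' @export
grid_code_config <- function(n_frequencies = 9L,
                             n_phases = 100L,
                             base_frequency = 0.0028 * 2 * pi,
                             frequency_ratio = 2,
                             space_extent = 1000L) {
  n_frequencies <- as.integer(n_frequencies)
  n_phases <- as.integer(n_phases)
  if (n_frequencies < 1L) stop("n_frequencies must be >= 1")
  if (n_phases < 1L) stop("n_phases must be >= 1")
  if (!is.finite(base_frequency) || base_frequency <= 0) {
    stop("base_frequency must be > 0")
  }
  if (!is.finite(frequency_ratio) || frequency_ratio <= 1) {
    stop("frequency_ratio must be > 1")
  }
  structure(
    list(
      n_frequencies = n_frequencies,
      n_phases = n_phases,
      base_frequency = base_frequency,
      frequency_ratio = frequency_ratio,
      space_extent = as.integer(space_extent)
    ),
    class = "grid_code_config"
  )
}

#' @export
print.grid_code_config <- function(x, ...) {
  cat(sprintf(
    "grid code: %d frequencies x %d phases = %d cells\n",
    x$n_frequencies, x$n_phases, x$n_frequencies * x$n_phases
  ))
  cat(sprintf(
    "  frequencies: %.6g .. %.6g rad/unit (ratio %g)\n",
    x$base_frequency,
    x$base_frequency * x$frequency_ratio^(x$n_frequencies - 1),
    x$frequency_ratio
  ))
  invisible(x)
}

#' Spatial frequencies of a grid code
#'
#' @param config a [grid_code_config()].
#' @return numeric vector of length `n_frequencies`, radians per unit length.
#' @export
grid_frequencies <- function(config) {
  config$base_frequency * config$frequency_ratio^(seq_len(config$n_frequencies) - 1)
}

#' Hexagonal basis vectors
#'
#' The three unit vectors at angles 0, pi/3 and 2*pi/3 whose cosine responses
#' sum to the hexagonally periodic firing pattern of a grid cell.
#'
#' @return a 2 x 3 matrix with columns b0, b1, b2.
#' @export
grid_basis <- function() {
  ang <- c(0, pi / 3, 2 * pi / 3)
  rbind(cos(ang), sin(ang))
}

#' Phase offset table
#'
#' Builds the `n_phases` phase offsets shared by every frequency: a regular
#' sqrt(Np) x sqrt(Np) lattice uniformly tiling one 2*pi x 2*pi period cell
#' of the phase space, anchored at the origin. Offsets are expressed in
#' radians and added after the location has been scaled by the frequency, so
#' the same table serves all frequencies and phase blocks are directly
#' comparable across frequencies.
#'
#' @param config a [grid_code_config()].
#' @return an `n_phases` x 2 matrix of radian offsets; first row is (0, 0).
#' @examples
#' off <- make_offsets(grid_code_config(n_phases = 4L))
#' off   # the four corners {0, pi}^2
#' @export
make_offsets <- function(config) {
  np <- config$n_phases
  side <- sqrt(np)
  if (side != floor(side)) {
    stop("n_phases must be a perfect square for the regular offset lattice")
  }
  side <- as.integer(side)
  step <- 2 * pi / side
  g <- (seq_len(side) - 1L) * step
  # column-major over the lattice: offset k = (g[row], g[col])
  cbind(rep(g, times = side), rep(g, each = side))
}

encode_prepared <- function(config, offsets) {
  B <- grid_basis()
  list(
    freqs = grid_frequencies(config),
    cosO = cos(offsets %*% B), # Np x 3
    sinO = sin(offsets %*% B),
    B = B
  )
}

#' Encode 2D locations as grid-cell firing rates
#'
#' For frequency f with spatial frequency F_f and phase offset o, the cell's
#' firing rate at location A is `max(0, cos(z0) + cos(z1) + cos(z2))` with
#' `zi = bi . (F_f * A + o)` and b0, b1, b2 the hexagonal basis of
#' [grid_basis()]. Rates therefore lie in [0, 3]. The embedding concatenates
#' per-frequency blocks of `n_phases` cells, lowest frequency first.
#'
#' `encode_batch()` encodes a matrix of locations row by row;
#' `encode_point()` is the single-location convenience wrapper.
#'
#' @param points numeric n x 2 matrix of locations (rows), or a length-2
#'   vector for `encode_point`.
#' @param config a [grid_code_config()].
#' @param offsets offset table from [make_offsets()].
#' @return `encode_batch`: an n x (Nf * Np) matrix of firing rates, row i
#'   encoding `points[i, ]`; `encode_point`: a numeric vector of length
#'   Nf * Np.
#' @examples
#' cfg <- grid_code_config(n_frequencies = 2L, n_phases = 4L)
#' off <- make_offsets(cfg)
#' encode_point(c(0, 0), cfg, off)
#' @export
encode_batch <- function(points, config, offsets) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must have two columns")
  if (nrow(points) > 0L) stopifnot_finite(points, "points")
  prep <- encode_prepared(config, offsets)
  n <- nrow(points)
  np <- config$n_phases
  out <- matrix(0, n, config$n_frequencies * np)
  if (n == 0L) return(out)
  for (f in seq_len(config$n_frequencies)) {
    P <- (points * prep$freqs[f]) %*% prep$B # n x 3 phase of each axis
    # cos(p + o) = cos p cos o - sin p sin o, summed over the three axes
    block <- cos(P) %*% t(prep$cosO) - sin(P) %*% t(prep$sinO)
    out[, ((f - 1L) * np + 1L):(f * np)] <- pmax(block, 0)
  }
  out
}

#' @rdname encode_batch
#' @param A numeric length-2 location.
#' @export
encode_point <- function(A, config, offsets) {
  if (length(A) != 2L || !all(is.finite(A))) {
    stop("A must be a finite 2-vector")
  }
  drop(encode_batch(matrix(A, 1L, 2L), config, offsets))
}

#' Extract one frequency block of an embedding
#'
#' Returns the `n_phases` cells belonging to frequency `f` (1-based). After
#' DPP attention has selected a frequency, this restriction — not elementwise
#' gating — is what feeds the downstream scorer.
#'
#' @param embedding numeric vector of length Nf * Np, or a matrix with
#'   Nf * Np columns (rows are embeddings).
#' @param f frequency index in `[1, Nf]`.
#' @param n_phases phases per frequency (Np).
#' @return vector of length Np, or matrix with Np columns.
#' @export
restrict_to_frequency <- function(embedding, f, n_phases) {
  f <- as.integer(f)
  idx <- ((f - 1L) * n_phases + 1L):(f * n_phases)
  if (is.null(dim(embedding))) {
    if (f < 1L || f * n_phases > length(embedding)) {
      stop("frequency index out of range")
    }
    embedding[idx]
  } else {
    if (f < 1L || f * n_phases > ncol(embedding)) {
      stop("frequency index out of range")
    }
    embedding[, idx, drop = FALSE]
  }
}
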