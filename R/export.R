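#' Column metadata and export for embedding matrices
#'
#' `embedding_column_info()` names every cell of the embedding: its
#' frequency index, spatial frequency (radians per unit), phase index
#' within the frequency, and the radian phase offset. `write_embeddings()`
#' writes a dense points-by-cells matrix as CSV together with a sidecar
#' header file carrying that per-column metadata.
#'
#' @param config a [grid_code_config()].
#' @param offsets offset table from [make_offsets()].
#' @return `embedding_column_info`: data frame with one row per cell
#'   (columns `cell`, `frequency_index`, `frequency`, `phase_index`,
#'   `offset_x`, `offset_y`).
#' @export
embedding_column_info <- function(config, offsets = make_offsets(config)) {
  freqs <- grid_frequencies(config)
  np <- config$n_phases
  data.frame(
    cell = seq_len(config$n_frequencies * np),
    frequency_index = rep(seq_len(config$n_frequencies), each = np),
    frequency = rep(freqs, each = np),
    phase_index = rep(seq_len(np), config$n_frequencies),
    offset_x = rep(offsets[, 1], config$n_frequencies),
    offset_y = rep(offsets[, 2], config$n_frequencies)
  )
}

#' @rdname embedding_column_info
#' @param points n x 2 matrix of locations to encode.
#' @param file output CSV path; the sidecar is written to
#'   `<file>.columns.csv`.
#' @return `write_embeddings`: the embedding matrix, invisibly.
#' @export
write_embeddings <- function(points, config, offsets = make_offsets(config),
                             file) {
  E <- encode_batch(points, config, offsets)
  utils::write.csv(E, file, row.names = FALSE)
  utils::write.csv(embedding_column_info(config, offsets),
                   paste0(file, ".columns.csv"), row.names = FALSE)
  invisible(E)
}
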