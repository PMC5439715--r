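#' Write an expression study to TSV files
#'
#' Writes the intensity matrix as a genes x samples TSV (first column
#' `gene`) and the sample sheet as a metadata TSV with columns `sample_id`,
#' `dose_gy`, `day`, `replicate`, `batch`.
#'
#' @param study An `expression_study`.
#' @param matrix_path,samples_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_study <- function(study, matrix_path, samples_path) {
  stopifnot(inherits(study, "expression_study"))
  mt <- dplyr::bind_cols(
    dplyr::tibble(gene = rownames(study$matrix)),
    dplyr::as_tibble(study$matrix)
  )
  readr::write_tsv(mt, matrix_path)
  readr::write_tsv(study$samples, samples_path)
  invisible(c(matrix_path, samples_path))
}

#' Read an expression study from TSV files
#'
#' @param matrix_path Genes x samples TSV whose first column holds gene ids.
#' @param samples_path Metadata TSV (`sample_id`, `dose_gy`, `day`,
#'   `replicate`, `batch`).
#' @return An `expression_study` (no ground-truth labels).
#' @export
read_expression_study <- function(matrix_path, samples_path) {
  mt <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  m <- as.matrix(mt[, -1])
  rownames(m) <- mt[[1]]
  if (!identical(colnames(m), samples$sample_id)) {
    m <- m[, samples$sample_id, drop = FALSE]
  }
  new_expression_study(m, samples)
}
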