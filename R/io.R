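#' Read and write per-cell score tables
#'
#' Tab-separated tables with columns `chip_id`, `well_id`,
#' `population_id`, `cell_id`, `s_epha` and optionally `s_epha_hat`.
#'
#' @param scores data.frame of scores.
#' @param path TSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write chip manifests
#'
#' A manifest maps wells to populations and flags the reference wells:
#' columns `chip_id`, `well_id`, `population_id`, `is_reference`.
#'
#' @param chip a `chip_record`.
#' @param path TSV path.
#' @export
write_chip_manifest <- function(chip, path) {
  wells <- unique(chip$cells[c("well_id", "population_id")])
  df <- data.frame(chip_id = chip$chip_id, wells,
                   is_reference = wells$well_id %in% chip$reference_wells,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chip_manifest
#' @export
read_chip_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Chip QC report as JSON
#'
#' One entry per chip: id, KW p-value, pass flag, reference mean and
#' reference cell count.
#'
#' @param chips list of `chip_record`s after QC / normalization.
#' @param path JSON path.
#' @export
write_qc_report <- function(chips, path) {
  rep <- lapply(chips, function(ch) list(
    chip_id = ch$chip_id, p = ch$qc_pvalue, pass = isTRUE(ch$qc_passed),
    reference_mean = ch$reference_mean,
    n_reference_cells = sum(ch$cells$well_id %in% ch$reference_wells)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write expression matrices
#'
#' TSV layout: genes as rows (first column `gene_id`), cells as columns.
#' The MTX layout is the standard MatrixMarket triple: matrix file plus
#' one-per-line gene and cell annotation files (cell annotation TSV with
#' columns `cell_id`, `line`, `class`).
#'
#' @param em an `expression_matrix`.
#' @param path TSV path.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param cell_annotation data.frame with columns `cell_id`, `line`,
#'   `class` (for the TSV reader, which carries no annotation itself).
#' @param already_log whether the stored values are log2(TPM+1).
#' @export
read_expression_tsv <- function(path, cell_annotation,
                                already_log = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  annotation_to_matrix(vals, cell_annotation, already_log)
}

#' @rdname write_expression_tsv
#' @param matrix_path,genes_path,cells_path the MatrixMarket triple.
#' @export
write_expression_mtx <- function(em, matrix_path, genes_path, cells_path) {
  Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), matrix_path)
  writeLines(em$gene_ids, genes_path)
  ann <- data.frame(cell_id = em$cell_ids,
                    line = unname(em$cell_line[em$cell_ids]),
                    class = unname(em$line_class[em$cell_line[em$cell_ids]]),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_mtx <- function(matrix_path, genes_path, cells_path,
                                already_log = TRUE) {
  vals <- as.matrix(Matrix::readMM(matrix_path))
  rownames(vals) <- readLines(genes_path)
  ann <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  colnames(vals) <- ann$cell_id
  annotation_to_matrix(vals, ann, already_log)
}

annotation_to_matrix <- function(vals, ann, already_log) {
  cell_line <- ann$line
  names(cell_line) <- ann$cell_id
  lc <- ann[!duplicated(ann$line), ]
  line_class <- lc$class
  names(line_class) <- lc$line
  expression_matrix(vals, cell_line = cell_line, line_class = line_class,
                    already_log = already_log)
}

#' Load a pathway gene list
#'
#' One gene id per line; blank lines and `#` comments ignored. The
#' package ships a synthetic placeholder list
#' (`inst/extdata/epha2_pathway_genes_synthetic.txt`) standing in for a
#' user-supplied EphA2-cascade gene set.
#'
#' @param path text file of gene ids.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
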