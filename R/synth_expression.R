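#' Parameters for a synthetic single-cell expression matrix
#'
#' Emulates a genes x cells log2(TPM+1) matrix in which a designated
#' pathway gene set has line-specific mean expression (coupled, in the
#' assay, to the receptor-clustering phenotype) while the remaining genes
#' share a common mean. Dropout zeroes entries at a fixed rate, the main
#' sparsity feature of plate-based scRNA-seq.
#'
#' @param n_genes total genes in the matrix.
#' @param pathway_gene_ids character ids of the pathway genes; must be a
#'   subset of the generated gene universe (`gene1..geneN` by default, or
#'   supply `gene_ids`).
#' @param n_cells_per_line cells per line.
#' @param line_pathway_means named numeric: mean log2(TPM+1) of pathway
#'   genes per line.
#' @param background_mean mean log-expression of non-pathway genes.
#' @param dispersion sd of log-expression around its mean.
#' @param dropout_rate probability an entry is zeroed.
#' @param gene_ids optional gene universe (length `n_genes`).
#' @param line_class optional named map line -> class
#'   (`"primary"`, `"metastatic"`, `"resistant"`).
#' @return an `expression_synth_params` object.
#' @export
expression_synth_params <- function(n_genes = 200L,
                                    pathway_gene_ids = sprintf("gene%d", 1:71),
                                    n_cells_per_line = 100L,
                                    line_pathway_means = c(lineA = 4, lineB = 6),
                                    background_mean = 2,
                                    dispersion = 0.5,
                                    dropout_rate = 0.1,
                                    gene_ids = NULL,
                                    line_class = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes,
            dropout_rate >= 0, dropout_rate <= 1, dispersion >= 0,
            length(line_pathway_means) >= 1,
            !is.null(names(line_pathway_means)))
  if (!all(pathway_gene_ids %in% gene_ids))
    stop("pathway_gene_ids must be a subset of the gene universe")
  if (is.null(line_class)) {
    line_class <- rep("primary", length(line_pathway_means))
    names(line_class) <- names(line_pathway_means)
  }
  structure(list(n_genes = as.integer(n_genes),
                 pathway_gene_ids = pathway_gene_ids,
                 n_cells_per_line = as.integer(n_cells_per_line),
                 line_pathway_means = line_pathway_means,
                 background_mean = background_mean,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 gene_ids = gene_ids, line_class = line_class),
            class = "expression_synth_params")
}

#' Generate a synthetic log-expression matrix
#'
#' @param params an [expression_synth_params()] object.
#' @param seed integer seed; identical matrix on re-run with fixed seed.
#' @return an [expression_matrix()] of log2(TPM+1) values with cell ->
#'   line labels attached.
#' @export
generate_expression_matrix <- function(params, seed = 1L) {
  stopifnot(inherits(params, "expression_synth_params"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  lines <- names(params$line_pathway_means)
  n_cells <- params$n_cells_per_line * length(lines)
  cell_ids <- sprintf("cell%d", seq_len(n_cells))
  cell_line <- rep(lines, each = params$n_cells_per_line)
  names(cell_line) <- cell_ids
  is_path <- params$gene_ids %in% params$pathway_gene_ids

  vals <- matrix(0, params$n_genes, n_cells,
                 dimnames = list(params$gene_ids, cell_ids))
  for (j in seq_len(n_cells)) {
    mu <- ifelse(is_path, params$line_pathway_means[[cell_line[j]]],
                 params$background_mean)
    vals[, j] <- pmax(stats::rnorm(params$n_genes, mu, params$dispersion), 0)
  }
  if (params$dropout_rate > 0)
    vals[stats::runif(length(vals)) < params$dropout_rate] <- 0
  expression_matrix(vals, cell_line = cell_line,
                    line_class = params$line_class, already_log = TRUE)
}
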