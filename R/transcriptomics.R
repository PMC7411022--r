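#' Single-cell expression matrix container
#'
#' Genes x cells matrix of log-expression values E = log2(TPM + 1), with
#' each cell assigned to a patient-derived line and each line to a class
#' (primary tumor, metastatic, or induced drug-resistant).
#'
#' @param values numeric genes x cells matrix (E >= 0) with gene ids as
#'   rownames and cell ids as colnames.
#' @param cell_line named character: cell id -> line id.
#' @param line_class named character: line id -> one of `"primary"`,
#'   `"metastatic"`, `"resistant"`.
#' @param already_log values are already log2(TPM+1) (the default);
#'   `FALSE` marks a raw-TPM matrix that still needs
#'   [to_log_expression()].
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, cell_line, line_class,
                              already_log = TRUE) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            all(values >= 0))
  if (!all(colnames(values) %in% names(cell_line)))
    stop("expression_matrix(): every cell needs a line label")
  lines <- unique(unname(cell_line[colnames(values)]))
  if (!all(lines %in% names(line_class)))
    stop("expression_matrix(): every line needs a class")
  bad <- setdiff(unique(line_class), c("primary", "metastatic", "resistant"))
  if (length(bad))
    stop("expression_matrix(): unknown line class: ", paste(bad, collapse = ", "))
  structure(list(values = values,
                 gene_ids = rownames(values), cell_ids = colnames(values),
                 cell_line = cell_line[colnames(values)],
                 line_class = line_class,
                 already_log = isTRUE(already_log)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells (", if (x$already_log) "log2(TPM+1)" else "raw TPM", ")\n")
  invisible(x)
}

#' Convert a raw TPM matrix to log expression
#'
#' Applies E = log2(TPM + 1) elementwise. Refuses to transform a matrix
#' already marked as log-scale, guarding against double transformation.
#'
#' @param em an `expression_matrix` with `already_log = FALSE`, or a raw
#'   TPM matrix (with dimnames) plus `cell_line`/`line_class`.
#' @inheritParams expression_matrix
#' @return an `expression_matrix` on the log scale.
#' @export
to_log_expression <- function(em, cell_line = NULL, line_class = NULL) {
  if (inherits(em, "expression_matrix")) {
    if (em$already_log)
      stop("to_log_expression(): input is already log2(TPM+1)")
    vals <- em$values; cell_line <- em$cell_line; line_class <- em$line_class
  } else {
    vals <- as.matrix(em)
  }
  if (any(vals < 0)) stop("to_log_expression(): negative TPM entries")
  expression_matrix(log2(vals + 1), cell_line = cell_line,
                    line_class = line_class, already_log = TRUE)
}

#' Select the pathway gene set and drop low-expression markers
#'
#' Restricts the matrix to the declared pathway genes (the EphA2
#' signaling cascade set in the source assay) and excludes markers whose
#' average log-expression across all cells falls below `min_avg` (kept
#' when mean E >= min_avg; the strict "lower than 1" reading). Genes
#' absent from the matrix are reported separately from genes excluded
#' for low expression.
#'
#' @param em a log-scale `expression_matrix`.
#' @param pathway_gene_ids character vector of pathway gene ids.
#' @param min_avg minimum mean log-expression (default 1).
#' @return list with `matrix` (the filtered `expression_matrix`) and
#'   `excluded` (data.frame `gene_id`, `reason` in
#'   `"absent"`/`"low_expression"`, `mean_expression`).
#' @export
pathway_filter <- function(em, pathway_gene_ids, min_avg = 1) {
  stopifnot(inherits(em, "expression_matrix"), em$already_log,
            length(pathway_gene_ids) >= 1)
  absent <- setdiff(pathway_gene_ids, em$gene_ids)
  present <- intersect(pathway_gene_ids, em$gene_ids)
  mexp <- rowMeans(em$values[present, , drop = FALSE])
  low <- present[mexp < min_avg]
  keep <- present[mexp >= min_avg]
  excluded <- rbind(
    if (length(absent))
      data.frame(gene_id = absent, reason = "absent",
                 mean_expression = NA_real_, stringsAsFactors = FALSE),
    if (length(low))
      data.frame(gene_id = low, reason = "low_expression",
                 mean_expression = unname(mexp[low]), stringsAsFactors = FALSE))
  if (is.null(excluded))
    excluded <- data.frame(gene_id = character(0), reason = character(0),
                           mean_expression = numeric(0))
  if (length(keep) == 0L)
    stop("pathway_filter(): no pathway gene survives the filter")
  sub <- expression_matrix(em$values[keep, , drop = FALSE],
                           cell_line = em$cell_line,
                           line_class = em$line_class, already_log = TRUE)
  list(matrix = sub, excluded = excluded)
}

#' Per-cell pathway score
#'
#' The single-cell genomic score: the unweighted arithmetic mean of
#' log-expression over the surviving pathway genes, per cell.
#'
#' @param em a filtered `expression_matrix` (>= 1 gene).
#' @return named numeric vector, cell id -> score.
#' @export
cell_scores <- function(em) {
  stopifnot(inherits(em, "expression_matrix"), nrow(em$values) >= 1)
  colMeans(em$values)
}

#' Discard low-score outlier cells
#'
#' Cells whose pathway score is strictly below the threshold are removed
#' before patient normalization (the study discarded 5 such cells at
#' threshold 3).
#'
#' @param scores named per-cell scores from [cell_scores()].
#' @param threshold strict lower cutoff (default 3).
#' @return list with `kept` and `discarded` (both named numeric).
#' @export
discard_low_epha2 <- function(scores, threshold = 3) {
  low <- scores < threshold
  if (all(low))
    stop("discard_low_epha2(): every cell falls below the threshold")
  list(kept = scores[!low], discarded = scores[low])
}

#' Normalize pathway scores by each patient's primary line
#'
#' Each patient's scores are divided by the mean score of that patient's
#' primary-line cells, removing individual genetic background: after
#' normalization every patient's primary-line mean is exactly 1 and
#' within-patient comparisons are scale-free. Patients are inferred from
#' line-id prefixes (e.g. `HN120p` / `HN120m` / `HN120pcr` share patient
#' `HN120`) unless an explicit map is given.
#'
#' @param scores named per-cell scores (after outlier removal).
#' @param cell_line named character cell -> line.
#' @param line_class named character line -> class.
#' @param patient_of optional named character line -> patient id,
#'   overriding prefix inference.
#' @return an `enrichment_result`: `cell_scores` (normalized),
#'   `raw_scores`, `per_line_means`, `normalized_line_means`,
#'   `normalization_factor` (per patient), `patient_of`.
#' @export
normalize_by_primary <- function(scores, cell_line, line_class,
                                 patient_of = NULL) {
  lines <- unique(unname(cell_line[names(scores)]))
  if (is.null(patient_of)) patient_of <- infer_patients(lines)
  if (!all(lines %in% names(patient_of)))
    stop("normalize_by_primary(): missing patient for line(s): ",
         paste(setdiff(lines, names(patient_of)), collapse = ", "))
  cl <- cell_line[names(scores)]
  patient <- patient_of[cl]
  primary <- line_class[cl] == "primary"
  factors <- tapply(scores[primary], patient[primary], mean)
  missing <- setdiff(unique(patient), names(factors))
  if (length(missing))
    stop("normalize_by_primary(): patient(s) without primary cells: ",
         paste(missing, collapse = ", "))
  norm <- as.vector(scores / factors[patient])
  names(norm) <- names(scores)
  structure(list(
    cell_scores = norm, raw_scores = scores,
    per_line_means = tapply(scores, cl, mean),
    normalized_line_means = tapply(norm, cl, mean),
    normalization_factor = factors,
    patient_of = patient_of), class = "enrichment_result")
}

#' Infer patient ids from line-id suffixes
#'
#' Strips a trailing line-class suffix (`p`, `m` or `pcr`,
#' case-insensitive) from each line id; ids without a recognized suffix
#' map to themselves.
#'
#' @param lines character vector of line ids.
#' @return named character, line -> patient.
#' @export
infer_patients <- function(lines) {
  out <- sub("(pcr|p|m)$", "", lines, ignore.case = TRUE)
  out[out == ""] <- lines[out == ""]
  names(out) <- lines
  out
}

#' Correlate line-level pathway scores with clustering scores
#'
#' Pearson correlation (with two-sided p) between per-line mean
#' transcriptomic enrichment scores and per-line mean normalized
#' clustering scores.
#'
#' @param enrichment_means named per-line enrichment means.
#' @param clustering_means named per-line clustering means (same lines).
#' @return list with `r`, `p` and `n_lines`.
#' @export
correlate_scores <- function(enrichment_means, clustering_means) {
  lines <- intersect(names(enrichment_means), names(clustering_means))
  if (length(lines) < 3)
    stop("correlate_scores(): need >= 3 lines in common")
  x <- as.numeric(enrichment_means[lines])
  y <- as.numeric(clustering_means[lines])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate_scores(): zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n_lines = length(lines))
}

#' Run the full enrichment pipeline on a matrix
#'
#' Fixed filter order: pathway gene selection -> low-expression gene
#' exclusion -> per-cell scoring -> low-score outlier discard -> patient
#' normalization.
#'
#' @param em log-scale `expression_matrix`.
#' @param pathway_gene_ids pathway gene ids.
#' @param min_avg gene-level mean-expression cutoff (default 1).
#' @param score_threshold cell-level outlier cutoff (default 3).
#' @param patient_of optional line -> patient map.
#' @return the `enrichment_result` with `excluded_genes` and
#'   `discarded_cells` attached.
#' @export
enrichment_pipeline <- function(em, pathway_gene_ids, min_avg = 1,
                                score_threshold = 3, patient_of = NULL) {
  flt <- pathway_filter(em, pathway_gene_ids, min_avg = min_avg)
  sc <- cell_scores(flt$matrix)
  split <- discard_low_epha2(sc, threshold = score_threshold)
  res <- normalize_by_primary(split$kept, em$cell_line, em$line_class,
                              patient_of = patient_of)
  res$excluded_genes <- flt$excluded
  res$discarded_cells <- split$discarded
  res
}
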