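test_that("log transform is exact and guarded against double application", {
  tpm <- matrix(c(0, 1, 3, 7), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  em <- to_log_expression(tpm, cell_line = c(c1 = "HN120p", c2 = "HN120p"),
                          line_class = c(HN120p = "primary"))
  expect_equal(unname(em$values), matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(to_log_expression(em), "already")
  # round trip recovers TPM
  expect_equal(2^em$values - 1, tpm, tolerance = 1e-9)
  tpm_neg <- tpm; tpm_neg[1, 1] <- -1
  expect_error(to_log_expression(tpm_neg,
                                 cell_line = c(c1 = "HN120p", c2 = "HN120p"),
                                 line_class = c(HN120p = "primary")),
               "negative")
})

test_that("pathway filter applies the mean-expression boundary strictly", {
  vals <- rbind(low = c(0.5, 0.5), boundary = c(1, 1), high = c(4, 6),
                other = c(2, 2))
  colnames(vals) <- c("c1", "c2")
  em <- toy_expression(vals, c(c1 = "L", c2 = "L"), c(L = "primary"))
  res <- pathway_filter(em, c("low", "boundary", "high", "ghost"))
  expect_setequal(rownames(res$matrix$values), c("boundary", "high"))
  expect_equal(nrow(res$excluded), 2L)
  expect_equal(res$excluded$reason[res$excluded$gene_id == "ghost"], "absent")
  expect_equal(res$excluded$reason[res$excluded$gene_id == "low"],
               "low_expression")
})

test_that("a 71-gene panel with planted failures filters to 63 genes", {
  set.seed(41)
  panel <- sprintf("EPHAPATH%02d", 1:71)
  present <- panel[1:68]            # 3 genes absent from the matrix
  n_cells <- 40
  vals <- matrix(rnorm(68 * n_cells, 4, 0.3), 68, n_cells,
                 dimnames = list(present, sprintf("c%d", 1:n_cells)))
  vals[64:68, ] <- abs(rnorm(5 * n_cells, 0.3, 0.1))  # 5 low-expression
  vals <- pmax(vals, 0)
  lines <- rep("HN120p", n_cells); names(lines) <- colnames(vals)
  em <- toy_expression(vals, lines, c(HN120p = "primary"))
  res <- pathway_filter(em, panel)
  expect_equal(nrow(res$matrix$values), 63L)
  expect_equal(nrow(res$excluded), 8L)
  expect_equal(sum(res$excluded$reason == "absent"), 3L)
  expect_equal(sum(res$excluded$reason == "low_expression"), 5L)
})

test_that("cell scores are per-cell linear averages over genes", {
  vals <- rbind(A = c(4, 6), C = c(4, 2))
  colnames(vals) <- c("c1", "c2")
  em <- toy_expression(vals, c(c1 = "L", c2 = "L"), c(L = "primary"))
  sc <- cell_scores(em)
  expect_equal(unname(sc), c(4, 4))
  # single gene: scores equal that gene's row
  em1 <- toy_expression(vals["A", , drop = FALSE],
                        c(c1 = "L", c2 = "L"), c(L = "primary"))
  expect_equal(unname(cell_scores(em1)), c(4, 6))
  # permuting gene order leaves scores unchanged
  em_perm <- toy_expression(vals[c("C", "A"), ],
                            c(c1 = "L", c2 = "L"), c(L = "primary"))
  expect_equal(cell_scores(em_perm), sc)
})

test_that("low-score outliers are discarded strictly below threshold", {
  sc <- c(a = 2.9, b = 3.0, c = 5.0)
  res <- discard_low_epha2(sc)
  expect_identical(names(res$discarded), "a")
  expect_identical(names(res$kept), c("b", "c"))
  expect_length(discard_low_epha2(sc, threshold = 0)$discarded, 0L)
  expect_error(discard_low_epha2(sc, threshold = 10), "every cell")
  # conservation: kept + discarded = input
  expect_equal(length(res$kept) + length(res$discarded), length(sc))
  # engineered matrix: exactly 5 of 100 cells below the cutoff
  set.seed(42)
  vals <- matrix(rnorm(10 * 100, 5, 0.2), 10, 100,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:100)))
  vals[, 1:5] <- abs(rnorm(10 * 5, 1, 0.2))
  lines <- rep("Lp", 100); names(lines) <- colnames(vals)
  em <- toy_expression(pmax(vals, 0), lines, c(Lp = "primary"))
  res2 <- discard_low_epha2(cell_scores(em))
  expect_length(res2$discarded, 5L)
  expect_setequal(names(res2$discarded), sprintf("c%d", 1:5))
})

test_that("primary normalization is per patient and scale-free", {
  sc <- c(p1 = 4, p2 = 4, m1 = 6)
  cl <- c(p1 = "HN120p", p2 = "HN120p", m1 = "HN120m")
  lc <- c(HN120p = "primary", HN120m = "metastatic")
  res <- normalize_by_primary(sc, cl, lc)
  expect_equal(unname(res$cell_scores), c(1, 1, 1.5))
  expect_equal(unname(res$normalized_line_means["HN120p"]), 1,
               tolerance = 1e-9)
  # patient inference from line suffixes
  expect_equal(unname(infer_patients(c("HN120p", "HN120m", "HN120pcr"))),
               rep("HN120", 3))
  # two patients normalize independently: scaling one patient's raw
  # scores leaves its normalized values unchanged
  sc2 <- c(a1 = 4, a2 = 8, b1 = 2, b2 = 3)
  cl2 <- c(a1 = "HN120p", a2 = "HN120m", b1 = "HN148p", b2 = "HN148m")
  lc2 <- c(HN120p = "primary", HN120m = "metastatic",
           HN148p = "primary", HN148m = "metastatic")
  r1 <- normalize_by_primary(sc2, cl2, lc2)
  sc3 <- sc2; sc3[c("b1", "b2")] <- 10 * sc3[c("b1", "b2")]
  r2 <- normalize_by_primary(sc3, cl2, lc2)
  expect_equal(r1$cell_scores[c("b1", "b2")], r2$cell_scores[c("b1", "b2")])
  expect_equal(r1$cell_scores[c("a1", "a2")], r2$cell_scores[c("a1", "a2")])
  # patient without primary cells
  expect_error(normalize_by_primary(c(x = 1), c(x = "HN999m"),
                                    c(HN999m = "metastatic")), "primary")
})

test_that("line-level correlation behaves at the exact extremes", {
  e <- c(l1 = 1, l2 = 2, l3 = 3, l4 = 4)
  expect_equal(correlate_scores(e, e * 2 + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_scores(e, -e)$r, -1, tolerance = 1e-12)
  expect_error(correlate_scores(e[1:2], e[1:2]), ">= 3")
  expect_error(correlate_scores(e, c(l1 = 1, l2 = 1, l3 = 1, l4 = 1)),
               "zero variance")
})

test_that("the enrichment pipeline conserves cells and fixes filter order", {
  ep <- expression_synth_params(
    n_genes = 120L, pathway_gene_ids = sprintf("gene%d", 1:40),
    n_cells_per_line = 30L,
    line_pathway_means = c(HN120p = 4, HN120m = 5.5, HN120pcr = 6.5),
    line_class = c(HN120p = "primary", HN120m = "metastatic",
                   HN120pcr = "resistant"),
    dispersion = 0.4, dropout_rate = 0.05)
  em <- generate_expression_matrix(ep, seed = 13)
  res <- enrichment_pipeline(em, ep$pathway_gene_ids)
  expect_equal(length(res$cell_scores) + length(res$discarded_cells),
               ncol(em$values))
  expect_equal(unname(res$normalized_line_means["HN120p"]), 1,
               tolerance = 1e-9)
  expect_gt(res$normalized_line_means["HN120pcr"],
            res$normalized_line_means["HN120m"])
  # permuting cells changes no score
  perm <- sample(ncol(em$values))
  em_p <- expression_matrix(em$values[, perm], em$cell_line, em$line_class)
  res_p <- enrichment_pipeline(em_p, ep$pathway_gene_ids)
  expect_equal(res_p$cell_scores[names(res$cell_scores)], res$cell_scores)
})

test_that("pathway score tracks the clustering phenotype across lines", {
  # eight lines whose pathway mean rises linearly with their clustering
  # score; moderate noise: strong line-level correlation in most seeds
  clust <- c(A = 0.2, B = 0.35, C = 0.5, D = 0.65, E = 0.8, F = 0.95,
             G = 1.1, H = 1.25)
  hits <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    means <- 3.5 + 2 * clust + rnorm(8, 0, 0.15)
    names(means) <- names(clust)
    ep <- expression_synth_params(
      n_genes = 100L, pathway_gene_ids = sprintf("gene%d", 1:30),
      n_cells_per_line = 25L, line_pathway_means = means,
      line_class = stats::setNames(rep("primary", 8), names(clust)),
      dispersion = 0.5, dropout_rate = 0.1)
    em <- generate_expression_matrix(ep, seed = 100 + s)
    flt <- pathway_filter(em, ep$pathway_gene_ids)
    sc <- cell_scores(flt$matrix)
    line_means <- tapply(sc, em$cell_line[names(sc)], mean)
    r <- correlate_scores(line_means, clust)$r
    if (r > 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
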