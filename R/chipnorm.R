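#' Chip quality gate on the reference triplicates
#'
#' A chip is usable only when its three reference wells are statistically
#' indistinguishable: a Kruskal-Wallis test across the triplicate score
#' samples must give p > alpha, otherwise the whole chip is excluded.
#' Dunn's pairwise z-tests (Bonferroni-adjusted over the 3 pairs) are
#' computed for diagnostics; the pass/fail decision uses only the
#' omnibus p-value.
#'
#' @param chip a `chip_record`.
#' @param alpha significance level of the gate (default 0.05).
#' @param min_cells minimum cells required per reference well.
#' @return the chip with `qc_passed`, `qc_pvalue` and `dunn_pvalues`
#'   filled in.
#' @export
chip_qc <- function(chip, alpha = 0.05, min_cells = 10L) {
  stopifnot(inherits(chip, "chip_record"))
  if (length(chip$reference_wells) < 3L)
    stop("chip_qc(): chip must designate 3 reference wells")
  groups <- lapply(chip$reference_wells, function(w)
    chip$cells$s_epha[chip$cells$well_id == w])
  n <- vapply(groups, length, integer(1))
  if (any(n < min_cells))
    stop("chip_qc(): reference well(s) with fewer than ", min_cells,
         " cells: ", paste(chip$reference_wells[n < min_cells],
                           collapse = ", "))
  kd <- kw_dunn(groups, alpha = alpha)
  chip$qc_pvalue <- kd$omnibus_p
  chip$qc_passed <- kd$omnibus_p > alpha
  chip$dunn_pvalues <- kd$p_matrix
  if (!chip$qc_passed)
    message("chip_qc(): chip ", chip$chip_id, " FAILED (KW p = ",
            signif(kd$omnibus_p, 3), "); exclude from analysis")
  chip
}

#' Normalize a chip by its reference-line mean
#'
#' The three reference-well score samples are pooled into a single
#' distribution and its arithmetic mean becomes the chip's normalization
#' factor: every cell on the chip (reference cells included) gets
#' `s_epha_hat = s_epha / reference_mean`. After normalization the pooled
#' reference mean is exactly 1, and any multiplicative chip effect common
#' to all wells cancels exactly.
#'
#' @param chip a `chip_record`, normally after [chip_qc()].
#' @param force normalize even if QC failed or was not run (logged
#'   warning).
#' @return the chip with `reference_mean` set and `s_epha_hat` filled for
#'   every cell.
#' @export
normalize_chip <- function(chip, force = FALSE) {
  stopifnot(inherits(chip, "chip_record"))
  if (!isTRUE(chip$qc_passed)) {
    if (!force)
      stop("normalize_chip(): chip ", chip$chip_id,
           " has not passed QC (run chip_qc(), or use force = TRUE)")
    warning("normalize_chip(): normalizing chip ", chip$chip_id,
            " despite QC state '", chip$qc_passed, "'")
  }
  ref <- chip$cells$s_epha[chip$cells$well_id %in% chip$reference_wells]
  m <- mean(ref)
  if (!is.finite(m) || m <= 0)
    stop("normalize_chip(): non-positive reference mean")
  chip$reference_mean <- m
  chip$cells$s_epha_hat <- chip$cells$s_epha / m
  chip
}

#' QC-gate and normalize a batch of chips
#'
#' Runs [chip_qc()] then [normalize_chip()] on every chip; chips failing
#' the gate are excluded and the exclusion rate reported (in the source
#' study fewer than 20% of chips failed).
#'
#' @param chips list of `chip_record`s.
#' @param alpha QC significance level.
#' @param min_cells minimum cells per reference well.
#' @return list with `chips` (accepted, normalized), `excluded`
#'   (chip ids) and `exclusion_rate`.
#' @export
batch_normalize <- function(chips, alpha = 0.05, min_cells = 10L) {
  stopifnot(length(chips) >= 1)
  out <- list(); excluded <- character(0)
  for (chip in chips) {
    chip <- chip_qc(chip, alpha = alpha, min_cells = min_cells)
    if (isTRUE(chip$qc_passed)) {
      out[[length(out) + 1L]] <- normalize_chip(chip)
    } else {
      excluded <- c(excluded, chip$chip_id)
    }
  }
  if (length(out) == 0L)
    stop("batch_normalize(): every chip failed QC")
  rate <- length(excluded) / length(chips)
  message(sprintf("batch_normalize(): excluded %d/%d chips (rate %.3f)",
                  length(excluded), length(chips), rate))
  list(chips = out, excluded = excluded, exclusion_rate = rate)
}

#' Pool normalized scores from chips into one table
#'
#' @param chips list of normalized `chip_record`s.
#' @return data.frame with `chip_id` plus the per-cell score columns.
#' @export
pooled_scores <- function(chips) {
  do.call(rbind, lapply(chips, function(ch)
    cbind(chip_id = ch$chip_id, ch$cells, stringsAsFactors = FALSE)))
}
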