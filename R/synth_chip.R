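#' Parameters for a synthetic 9-well chip
#'
#' A chip holds nine independent recording chambers; three wells carry
#' triplicates of the reference cell line and the rest carry the test
#' populations. Day-to-day fluctuations of the detection system are
#' modeled as a single multiplicative gain applied to every per-cell
#' score on the chip (the entropy score is invariant to intensity gain,
#' so the chip effect acts at the score level).
#'
#' @param wells_per_population named list mapping population id to the
#'   well indices it occupies.
#' @param reference_population population id of the reference line.
#' @param reference_wells exactly 3 distinct well indices carrying the
#'   reference population.
#' @param n_wells number of wells on the chip (default 9).
#' @param cells_per_well cells measured per well (default 100).
#' @param chip_gain positive multiplicative chip effect on scores.
#' @param chip_id identifier.
#' @return a `chip_synth_params` object.
#' @export
chip_synth_params <- function(wells_per_population = list(MDA_MB231 = 1:3,
                                                          test = 4:9),
                              reference_population = "MDA_MB231",
                              reference_wells = 1:3, n_wells = 9L,
                              cells_per_well = 100L, chip_gain = 1,
                              chip_id = "chip1") {
  stopifnot(chip_gain > 0,
            length(reference_wells) == 3L,
            !anyDuplicated(reference_wells),
            all(reference_wells >= 1), all(reference_wells <= n_wells))
  if (!reference_population %in% names(wells_per_population))
    stop("reference_population '", reference_population,
         "' missing from wells_per_population")
  if (!all(reference_wells %in% wells_per_population[[reference_population]]))
    stop("reference_wells must carry the reference population")
  occupied <- unlist(wells_per_population)
  if (anyDuplicated(occupied)) stop("a well is assigned to two populations")
  if (any(occupied < 1 | occupied > n_wells)) stop("well index out of range")
  structure(list(wells_per_population = wells_per_population,
                 reference_population = reference_population,
                 reference_wells = reference_wells, n_wells = n_wells,
                 cells_per_well = cells_per_well, chip_gain = chip_gain,
                 chip_id = chip_id),
            class = "chip_synth_params")
}

#' Score-level population profile
#'
#' Fast sampler for a population's raw entropy-score distribution,
#' lognormal with the given log-mean and log-sd. Use [fit_score_profile()]
#' to fit one to the image-level pipeline's output so the two chip paths
#' agree in distribution.
#'
#' @param meanlog,sdlog lognormal parameters of the raw score.
#' @return a `score_profile` object.
#' @export
score_profile <- function(meanlog = log(1), sdlog = 0.4) {
  stopifnot(sdlog >= 0)
  structure(list(meanlog = meanlog, sdlog = sdlog), class = "score_profile")
}

#' Fit a score-level profile to the image-level pipeline
#'
#' Renders `n` cells with [generate_cell_image()], scores them through
#' [extract_cells()] + [score_cells()], and fits a lognormal to the
#' resulting scores by moments of the log.
#'
#' @param cell_params a [cell_synth_params()] object.
#' @param n number of cells rendered for the fit.
#' @param seed integer seed.
#' @param min_area passed to [extract_cells()].
#' @return a [score_profile()] with the fitted parameters; the fitted raw
#'   scores are attached as attribute `"scores"`.
#' @export
fit_score_profile <- function(cell_params, n = 100L, seed = 1L,
                              min_area = 200L) {
  s <- image_path_scores(cell_params, n, seed, min_area)
  out <- score_profile(meanlog = mean(log(s)), sdlog = stats::sd(log(s)))
  attr(out, "scores") <- s
  out
}

image_path_scores <- function(cell_params, n, seed, min_area = 200L) {
  vapply(seq_len(n), function(i) {
    im <- generate_cell_image(cell_params, seed = seed * 100000L + i)
    rec <- extract_cells(im$field, im$mask, min_area = min_area)
    score_cells(rec)$s_epha[1]
  }, numeric(1))
}

#' Simulate one chip of per-cell scores
#'
#' Fills every well with `cells_per_well` cells of its population, either
#' by the fast score-level path (profile is a [score_profile()]) or by the
#' full image-level path (profile is a [cell_synth_params()]: render,
#' extract, score). Every raw score on the chip is multiplied by the
#' chip's gain — the same gain for all wells.
#'
#' @param params a [chip_synth_params()] object.
#' @param population_profiles named list mapping each population id in
#'   `params$wells_per_population` to its profile.
#' @param seed integer seed; fixed seed gives identical chips.
#' @return a `chip_record` (see [chip_record()]).
#' @export
generate_chip <- function(params, population_profiles, seed = 1L) {
  stopifnot(inherits(params, "chip_synth_params"))
  missing_prof <- setdiff(names(params$wells_per_population),
                          names(population_profiles))
  if (length(missing_prof))
    stop("missing profile for population(s): ",
         paste(missing_prof, collapse = ", "))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  rows <- list()
  for (pop in names(params$wells_per_population)) {
    prof <- population_profiles[[pop]]
    for (w in params$wells_per_population[[pop]]) {
      raw <- if (inherits(prof, "score_profile")) {
        stats::rlnorm(params$cells_per_well, prof$meanlog, prof$sdlog)
      } else if (inherits(prof, "cell_synth_params")) {
        img_seed <- sample.int(.Machine$integer.max %/% 200000L, 1L)
        image_path_scores(prof, params$cells_per_well, img_seed)
      } else stop("profile for '", pop,
                  "' must be a score_profile or cell_synth_params")
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("w%d", w), population_id = pop,
        cell_id = seq_along(raw), s_epha = raw * params$chip_gain,
        s_epha_hat = NA_real_, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  cells <- cells[order(cells$well_id, cells$cell_id), ]
  rownames(cells) <- NULL
  chip_record(chip_id = params$chip_id, cells = cells,
              reference_wells = sprintf("w%d", params$reference_wells),
              reference_population = params$reference_population,
              chip_gain = params$chip_gain)
}

#' Chip record container
#'
#' Holds one chip's per-cell scores plus the reference-well designation
#' and the quality-control / normalization state filled in by
#' [chip_qc()] and [normalize_chip()].
#'
#' @param chip_id identifier.
#' @param cells data.frame with columns `well_id`, `population_id`,
#'   `cell_id`, `s_epha`, `s_epha_hat`.
#' @param reference_wells character vector of exactly 3 well ids, all
#'   carrying the reference population.
#' @param reference_population reference population id.
#' @param chip_gain simulated gain when known (`NA` for real data).
#' @return a `chip_record` object.
#' @export
chip_record <- function(chip_id, cells, reference_wells,
                        reference_population, chip_gain = NA_real_) {
  stopifnot(is.data.frame(cells),
            all(c("well_id", "population_id", "cell_id", "s_epha") %in%
                  names(cells)),
            length(reference_wells) == 3L)
  if (!all(reference_wells %in% cells$well_id))
    stop("reference well(s) absent from chip: ",
         paste(setdiff(reference_wells, cells$well_id), collapse = ", "))
  ref_pops <- unique(cells$population_id[cells$well_id %in% reference_wells])
  if (!identical(ref_pops, reference_population))
    stop("reference wells must all carry population '",
         reference_population, "'")
  if (!"s_epha_hat" %in% names(cells)) cells$s_epha_hat <- NA_real_
  structure(list(chip_id = chip_id, cells = cells,
                 reference_wells = reference_wells,
                 reference_population = reference_population,
                 chip_gain = chip_gain,
                 qc_passed = NA, qc_pvalue = NA_real_,
                 dunn_pvalues = NULL, reference_mean = NA_real_),
            class = "chip_record")
}

#' @export
print.chip_record <- function(x, ...) {
  cat("chip_record", x$chip_id, "-", nrow(x$cells), "cells,",
      length(unique(x$cells$well_id)), "wells\n")
  cat("  reference:", x$reference_population, "in",
      paste(x$reference_wells, collapse = ", "), "\n")
  if (!is.na(x$qc_passed))
    cat("  QC:", if (isTRUE(x$qc_passed)) "pass" else "FAIL",
        sprintf("(KW p = %.3g)", x$qc_pvalue), "\n")
  if (!is.na(x$reference_mean))
    cat(sprintf("  reference mean = %.4f (normalized)\n", x$reference_mean))
  invisible(x)
}
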