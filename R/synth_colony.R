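#' Parameters for a clonal-colony score series
#'
#' Emulates the clonal-expansion experiment: single founder cells picked
#' from an unsorted population are grown into colonies, scored after 10
#' days and again after 20 days. At day 10 each colony's scores stay
#' narrowly centered on its founder's phenotype (inheritance); by day 20
#' colonies drift back toward the population distribution (loss of
#' clonal memory), controlled by the convergence weight.
#'
#' @param population_scores numeric vector: the unsorted baseline
#'   distribution of normalized scores.
#' @param n_colonies number of surviving colonies (>= 2; the study grew 9).
#' @param founders optional founder scores; default: drawn from the
#'   baseline when the series is generated.
#' @param intra_colony_sd_day10 within-colony score sd at day 10.
#' @param convergence_weight_day20 mixture weight w in \[0, 1\] for day 20:
#'   each cell is drawn from the baseline with probability w, from its
#'   colony's day-10 law with probability 1 - w (0 = no drift, 1 = fully
#'   reverted to baseline).
#' @param cells_per_colony_per_day cells scored per colony per time point.
#' @return a `colony_synth_params` object.
#' @export
colony_synth_params <- function(population_scores, n_colonies = 9L,
                                founders = NULL,
                                intra_colony_sd_day10 = 0.05,
                                convergence_weight_day20 = 0.8,
                                cells_per_colony_per_day = 30L) {
  stopifnot(length(population_scores) > 0, n_colonies >= 2,
            convergence_weight_day20 >= 0, convergence_weight_day20 <= 1,
            intra_colony_sd_day10 >= 0, cells_per_colony_per_day >= 2)
  if (!is.null(founders)) stopifnot(length(founders) == n_colonies)
  structure(list(population_scores = as.numeric(population_scores),
                 n_colonies = as.integer(n_colonies), founders = founders,
                 intra_colony_sd_day10 = intra_colony_sd_day10,
                 convergence_weight_day20 = convergence_weight_day20,
                 cells_per_colony_per_day = as.integer(cells_per_colony_per_day)),
            class = "colony_synth_params")
}

#' Generate a clonal colony series
#'
#' For each colony: day-10 scores are founder-centered Gaussians with the
#' day-10 sd (truncated at zero, scores are non-negative); day-20 scores
#' come from the mixture `(1 - w) * colony-centered + w * baseline` with
#' `w = convergence_weight_day20`, baseline draws taken with replacement
#' from the supplied population scores.
#'
#' @param params a [colony_synth_params()] object.
#' @param seed integer seed; reproducible series under a fixed seed.
#' @return a `colony_series`: list with `colonies` (each `colony_id`,
#'   `founder`, `day10`, `day20` score vectors) and `baseline`.
#' @export
generate_colony_series <- function(params, seed = 1L) {
  stopifnot(inherits(params, "colony_synth_params"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  founders <- params$founders
  if (is.null(founders))
    founders <- sample(params$population_scores, params$n_colonies,
                       replace = FALSE)
  n <- params$cells_per_colony_per_day
  colonies <- lapply(seq_len(params$n_colonies), function(i) {
    d10 <- pmax(stats::rnorm(n, founders[i], params$intra_colony_sd_day10), 0)
    from_base <- stats::runif(n) < params$convergence_weight_day20
    d20 <- ifelse(from_base,
                  sample(params$population_scores, n, replace = TRUE),
                  pmax(stats::rnorm(n, founders[i],
                                    params$intra_colony_sd_day10), 0))
    list(colony_id = sprintf("colony%d", i), founder = founders[i],
         day10 = d10, day20 = d20)
  })
  structure(list(colonies = colonies,
                 baseline = params$population_scores),
            class = "colony_series")
}

#' @export
print.colony_series <- function(x, ...) {
  cat("colony_series:", length(x$colonies), "colonies,",
      length(x$baseline), "baseline cells\n")
  invisible(x)
}
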