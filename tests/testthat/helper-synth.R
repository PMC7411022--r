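# shared fixtures, built in code at test time

# small, fast render settings for image-based tests
small_cell_params <- function(...) {
  cell_synth_params(field_size_px = 160, cell_radius_px = 45, ...)
}

# unsorted-population baseline of normalized scores (right-skewed,
# spanning ~0.1-1.5 like a heterogeneous mesenchymal-type line)
make_baseline <- function(n = 300, seed = 1) {
  set.seed(seed)
  stats::rlnorm(n, log(0.45), 0.45)
}

# score-level population profiles used across chip tests
ref_profile <- function() score_profile(log(1), 0.4)
test_profile <- function() score_profile(log(0.6), 0.35)

# build a chip_record directly from per-well score vectors
chip_from_wells <- function(well_scores, reference_wells = names(well_scores)[1:3],
                            reference_population = "ref", chip_id = "chipX") {
  cells <- do.call(rbind, lapply(names(well_scores), function(w) {
    pop <- if (w %in% reference_wells) reference_population else "test"
    data.frame(well_id = w, population_id = pop,
               cell_id = seq_along(well_scores[[w]]),
               s_epha = well_scores[[w]], s_epha_hat = NA_real_,
               stringsAsFactors = FALSE)
  }))
  chip_record(chip_id, cells, reference_wells, reference_population)
}

# hand-built expression matrix fixture
toy_expression <- function(values, lines, classes) {
  expression_matrix(values, cell_line = lines, line_class = classes,
                    already_log = TRUE)
}
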