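#' Parameters for a synthetic single-cell fluorescence image
#'
#' Describes one cell carrying fluorescent puncta whose spatial
#' aggregation is tunable from scattered small puncta (`aggregation = 0`)
#' to a few large central aggregates (`aggregation = 1`) at conserved
#' total signal: aggregation redistributes photons, it never adds them.
#'
#' @param cell_radius_px cell radius in pixels.
#' @param n_puncta number of puncta (>= 1).
#' @param aggregation mixture weight in \[0, 1\]: each punctum joins one of
#'   at most 3 aggregate centers with this probability, otherwise it lands
#'   uniformly inside the cell.
#' @param total_signal expected integrated foreground signal (photon-count
#'   equivalent) summed over the whole cell.
#' @param punctum_sigma_px Gaussian width of a scattered punctum; 0 gives
#'   a delta-like single hot pixel.
#' @param aggregate_sigma_px Gaussian width of an aggregate.
#' @param background_level additive background counts.
#' @param noise_model one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_scale sd of Gaussian noise (ignored for the other models).
#' @param field_size_px side of the square field.
#' @return a `cell_synth_params` object.
#' @export
cell_synth_params <- function(cell_radius_px = 60, n_puncta = 40,
                              aggregation = 0.5, total_signal = 2e5,
                              punctum_sigma_px = 2, aggregate_sigma_px = 4,
                              background_level = 100,
                              noise_model = c("poisson", "gaussian", "none"),
                              noise_scale = 0, field_size_px = 256) {
  noise_model <- match.arg(noise_model)
  p <- structure(list(cell_radius_px = cell_radius_px, n_puncta = n_puncta,
                      aggregation = aggregation, total_signal = total_signal,
                      punctum_sigma_px = punctum_sigma_px,
                      aggregate_sigma_px = aggregate_sigma_px,
                      background_level = background_level,
                      noise_model = noise_model, noise_scale = noise_scale,
                      field_size_px = field_size_px),
                 class = "cell_synth_params")
  validate_cell_synth_params(p)
  p
}

validate_cell_synth_params <- function(p) {
  stopifnot(p$aggregation >= 0, p$aggregation <= 1,
            p$total_signal > 0, p$n_puncta >= 1,
            p$noise_scale >= 0, p$cell_radius_px > 0)
  if (p$cell_radius_px < 2 * p$punctum_sigma_px)
    stop("cell mask too small to place puncta: cell_radius_px < 2*punctum_sigma_px")
  # aggregation raises the score only when stacking puncta into <= 3
  # aggregates concentrates signal relative to scattered puncta
  if (p$punctum_sigma_px > 0 &&
      3 * p$aggregate_sigma_px^2 >= p$n_puncta * p$punctum_sigma_px^2)
    warning("aggregates do not concentrate signal: ",
            "3*aggregate_sigma_px^2 >= n_puncta*punctum_sigma_px^2; ",
            "expected score will not increase with aggregation")
  invisible(p)
}

#' Render a synthetic single-cell field and its label mask
#'
#' Draws one circular cell (label 1) centered in the field. The total
#' signal is split equally over `n_puncta` puncta; each punctum is
#' assigned with probability `aggregation` to one of at most 3 aggregate
#' centers drawn within the inner 50% radius of the cell (emulating the
#' inward transport of receptor clusters), otherwise its center is
#' uniform over the cell mask. Punctum mass is deposited as a discretized
#' Gaussian normalized to carry exactly its share of the signal, so the
#' expected integrated foreground signal is independent of aggregation.
#' Background and the chosen noise model are applied last and the field
#' is clamped to the 16-bit range.
#'
#' @param params a [cell_synth_params()] object.
#' @param seed integer seed; fixed seed gives a bit-identical field+mask.
#' @return list with `field` (a `fluorescence_field`) and `mask`
#'   (a `label_mask` with exactly one cell).
#' @export
generate_cell_image <- function(params = cell_synth_params(), seed = 1L) {
  validate_cell_synth_params(params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  n <- params$field_size_px
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  dist2 <- (rr - ctr)^2 + (cc - ctr)^2
  inside <- dist2 <= params$cell_radius_px^2
  mask <- matrix(0L, n, n)
  mask[inside] <- 1L

  img <- matrix(0, n, n)
  mass <- params$total_signal / params$n_puncta

  n_agg <- min(3L, max(1L, params$n_puncta))
  agg_centers <- draw_points_in_disk(n_agg, ctr, 0.5 * params$cell_radius_px)
  is_agg <- stats::runif(params$n_puncta) < params$aggregation
  for (i in seq_len(params$n_puncta)) {
    if (is_agg[i]) {
      k <- sample.int(n_agg, 1L)
      img <- deposit_gaussian(img, agg_centers[k, 1], agg_centers[k, 2],
                              params$aggregate_sigma_px, mass)
    } else {
      p <- draw_points_in_disk(1L, ctr, params$cell_radius_px)
      img <- deposit_gaussian(img, p[1, 1], p[1, 2],
                              params$punctum_sigma_px, mass)
    }
  }

  img <- img + params$background_level
  img <- switch(params$noise_model,
    none = img,
    gaussian = img + stats::rnorm(length(img), 0, params$noise_scale),
    poisson = matrix(stats::rpois(length(img), lambda = pmax(img, 0)),
                     nrow(img), ncol(img)))
  img <- pmin(pmax(round(img), 0), 65535)

  list(field = fluorescence_field(img, bit_depth = 16L),
       mask = label_mask(mask))
}

# uniform points in a disk (row, col) around (ctr, ctr)
draw_points_in_disk <- function(k, ctr, radius) {
  r <- radius * sqrt(stats::runif(k))
  th <- stats::runif(k, 0, 2 * pi)
  cbind(ctr + r * cos(th), ctr + r * sin(th))
}

# add a Gaussian blob of integrated mass `mass` at (r0, c0); the stamp is
# renormalized so the deposited mass is exact even near the field border
deposit_gaussian <- function(img, r0, c0, sigma, mass) {
  n <- nrow(img)
  if (sigma <= 0) {
    r <- min(max(round(r0), 1L), n); c <- min(max(round(c0), 1L), n)
    img[r, c] <- img[r, c] + mass
    return(img)
  }
  half <- ceiling(4 * sigma)
  rs <- max(1L, floor(r0) - half):min(n, ceiling(r0) + half)
  cs <- max(1L, floor(c0) - half):min(n, ceiling(c0) + half)
  g <- exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + mass * g / sum(g)
  img
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
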