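#' Detect fluorescent puncta inside one cell
#'
#' Thresholds the cell's pixels at
#' `background + relative_threshold * (max - background)` (max taken over
#' the cell), labels the suprathreshold pixels by 8-connectivity and
#' discards components smaller than 4 px. Supports the descriptor bank;
#' the entropy score itself never uses spot detection.
#'
#' @param field a `fluorescence_field`.
#' @param mask matching `label_mask`.
#' @param cell_id label of the cell to analyze.
#' @param relative_threshold in (0, 1); default 0.5.
#' @param background background level; field-median estimate when `NULL`.
#' @return list with `labels` (integer matrix, 0 outside puncta),
#'   `count`, `areas` (px per punctum) and `centroids` (count x 2 matrix
#'   of row/col).
#' @export
detect_puncta <- function(field, mask, cell_id = 1L,
                          relative_threshold = 0.5, background = NULL) {
  stopifnot(relative_threshold > 0, relative_threshold < 1)
  check_same_shape(field, mask)
  inside <- mask$labels == cell_id
  if (!any(inside)) stop("detect_puncta(): no pixels with label ", cell_id)
  if (is.null(background)) background <- estimate_background(field, mask)
  cellpx <- field$pixels[inside]
  vmax <- max(cellpx)
  # a contrast-free cell has no puncta: nothing stands out from the
  # cell's own signal, even when the cell as a whole is above background
  if (vmax == min(cellpx))
    return(list(labels = matrix(0L, nrow(field$pixels), ncol(field$pixels)),
                count = 0L, areas = integer(0),
                centroids = matrix(numeric(0), 0, 2)))
  thr <- background + relative_threshold * (vmax - background)
  bin <- matrix(0L, nrow(field$pixels), ncol(field$pixels))
  bin[inside & field$pixels > thr] <- 1L
  lab <- label_components8(bin)
  # drop specks (< 4 px)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    lab[lab %in% which(sizes < 4L)] <- 0L
    lab <- relabel_sequential(lab)
  }
  k <- max(lab)
  if (k == 0L)
    return(list(labels = lab, count = 0L, areas = integer(0),
                centroids = matrix(numeric(0), 0, 2)))
  areas <- tabulate(lab[lab > 0], nbins = k)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  centroids <- cbind(tapply(idx[, 1], l, mean), tapply(idx[, 2], l, mean))
  list(labels = lab, count = k, areas = areas, centroids = centroids)
}

# 8-connectivity labeling: 4-connected labeling (EBImage::bwlabel), then
# merge labels that touch diagonally via union-find over label ids
label_components8 <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  k <- max(lab)
  if (k <= 1) return(relabel_sequential(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  relabel_sequential(out)
}

#' Morphological descriptor bank for one cell
#'
#' Computes a fixed, documented set of per-cell descriptors of the
#' cluster pattern, used to rank which features separate populations.
#' All intensities are background-subtracted (floored at 0) first.
#' Descriptors:
#' \describe{
#'   \item{s_epha}{the intensity-entropy clustering score, [sepha()].}
#'   \item{mean_intensity, sd_intensity, cv_intensity, skewness,
#'     kurtosis}{moments of the intensity distribution (excess kurtosis).}
#'   \item{top_decile_fraction}{fraction of total signal carried by the
#'     brightest 10\% of pixels (~0.1 for uniform signal).}
#'   \item{punctum_count, punctum_mean_area, punctum_max_area,
#'     punctum_area_fraction}{spot statistics from [detect_puncta()] at
#'     the configured relative threshold (all 0 when nothing detected).}
#'   \item{radial_frac_25, radial_frac_50, radial_frac_75}{fraction of
#'     signal within 25/50/75\% of the normalized cell radius (distance
#'     from the intensity-free mask centroid, scaled by the mask's
#'     maximal radius).}
#'   \item{nn_dist_mean, nn_dist_min}{nearest-neighbor distance
#'     statistics of punctum centroids (0 with fewer than 2 puncta).}
#'   \item{area_px, eccentricity}{cell size and shape (from the mask's
#'     second moments).}
#' }
#'
#' @param field a `fluorescence_field`.
#' @param mask matching `label_mask`.
#' @param cell_id label of the cell.
#' @param relative_threshold passed to [detect_puncta()].
#' @return named numeric vector of descriptors (identical names for
#'   every cell of a run).
#' @export
descriptor_bank <- function(field, mask, cell_id = 1L,
                            relative_threshold = 0.5) {
  check_same_shape(field, mask)
  inside <- mask$labels == cell_id
  if (!any(inside)) stop("descriptor_bank(): no pixels with label ", cell_id)
  bg <- estimate_background(field, mask)
  v <- pmax(as.numeric(field$pixels[inside]) - bg, 0)
  n <- length(v)
  m <- mean(v); s <- stats::sd(v)
  z <- if (s > 0) (v - m) / s else rep(0, n)
  total <- sum(v)

  n_top <- ceiling(0.1 * n)
  top_frac <- if (total > 0) sum(sort(v, decreasing = TRUE)[seq_len(n_top)]) /
    total else 0

  pk <- tryCatch(
    detect_puncta(field, mask, cell_id, relative_threshold, background = bg),
    error = function(e) list(count = 0L, areas = integer(0),
                             centroids = matrix(numeric(0), 0, 2)))

  idx <- which(inside, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  dmax <- max(d)
  rnorm_d <- if (dmax > 0) d / dmax else rep(0, n)
  radial <- vapply(c(0.25, 0.5, 0.75), function(q)
    if (total > 0) sum(v[rnorm_d <= q]) / total else 0, numeric(1))

  nn <- c(mean = 0, min = 0)
  if (pk$count >= 2) {
    dd <- as.matrix(stats::dist(pk$centroids))
    diag(dd) <- Inf
    nnd <- apply(dd, 1, min)
    nn <- c(mean = mean(nnd), min = min(nnd))
  }

  cr <- idx[, 1] - ctr[1]; cc <- idx[, 2] - ctr[2]
  cov <- matrix(c(mean(cr^2), mean(cr * cc), mean(cr * cc), mean(cc^2)), 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0

  c(s_epha = if (m > 0) sepha(v) else 0,
    mean_intensity = m, sd_intensity = s,
    cv_intensity = if (m > 0) s / m else 0,
    skewness = if (s > 0) mean(z^3) else 0,
    kurtosis = if (s > 0) mean(z^4) - 3 else 0,
    top_decile_fraction = top_frac,
    punctum_count = pk$count,
    punctum_mean_area = if (pk$count) mean(pk$areas) else 0,
    punctum_max_area = if (pk$count) max(pk$areas) else 0,
    punctum_area_fraction = sum(pk$areas) / n,
    radial_frac_25 = radial[1], radial_frac_50 = radial[2],
    radial_frac_75 = radial[3],
    nn_dist_mean = nn[["mean"]], nn_dist_min = nn[["min"]],
    area_px = n, eccentricity = ecc)
}
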