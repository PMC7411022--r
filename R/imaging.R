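#' Read and write grayscale fluorescence fields
#'
#' Fields are single-channel 8- or 16-bit grayscale TIFFs holding raw
#' detector counts. Round trips are lossless at the declared bit depth.
#'
#' @param path path to a grayscale TIFF.
#' @return `read_field()` returns a `fluorescence_field`: a list with
#'   `pixels` (integer matrix of counts, rows = image rows, origin top
#'   left), `bit_depth` and `pixel_size_um` (`NA` when unknown).
#' @export
read_field <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  if (length(dim(px)) != 2L)
    stop("read_field(): '", path, "' is not single-channel grayscale (",
         paste(dim(px), collapse = "x"), ")")
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255L) 16L else 8L
  fluorescence_field(px, bit_depth = bits)
}

#' @rdname read_field
#' @param field a `fluorescence_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "fluorescence_field"))
  scale <- 2^field$bit_depth - 1
  tiff::writeTIFF(field$pixels / scale, path,
                  bits.per.sample = as.integer(field$bit_depth))
  invisible(path)
}

#' Construct a fluorescence field in memory
#'
#' @param pixels non-negative numeric/integer matrix of intensities.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um physical pixel size, `NA` when unknown.
#' @return a `fluorescence_field` object.
#' @export
fluorescence_field <- function(pixels, bit_depth = 16L, pixel_size_um = NA_real_) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0))
    stop("fluorescence_field(): intensities must be finite and >= 0")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um),
            class = "fluorescence_field")
}

#' Read and validate a cell label mask
#'
#' A label mask is an integer image the same shape as its field: 0 marks
#' background, cells are coded with ascending natural numbers 1..K with
#' no gaps (each label present as a nonempty pixel set).
#'
#' @param path integer-typed grayscale TIFF.
#' @return a `label_mask`: list with `labels` (integer matrix) and
#'   `n_cells`.
#' @export
read_mask <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2L)
    stop("read_mask(): '", path, "' is not single-channel")
  if (!is.integer(px) && any(px != round(px)))
    stop("read_mask(): mask is float-valued, expected integer labels")
  label_mask(px)
}

#' @rdname read_mask
#' @param labels integer matrix of labels (in-memory constructor; applies
#'   the same validation as `read_mask`).
#' @export
label_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (any(labels != round(labels)))
    stop("label_mask(): labels must be integers")
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("label_mask(): negative labels")
  present <- sort(unique(labels[labels > 0L]))
  k <- length(present)
  if (k > 0L && !identical(present, seq_len(max(present)))) {
    missing <- setdiff(seq_len(max(present)), present)
    stop("label_mask(): missing label ", paste(missing, collapse = ", "),
         " (labels must be 0 plus a gapless 1..K)")
  }
  structure(list(labels = labels, n_cells = k), class = "label_mask")
}

#' @rdname read_mask
#' @param mask a `label_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("write_mask(): >65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Field-level background estimate
#'
#' Median intensity over background (label-0) pixels. The entropy score is
#' sensitive to additive offsets, so a robust per-field background
#' estimate is subtracted by default before scoring.
#'
#' @param field a `fluorescence_field`.
#' @param mask matching `label_mask`.
#' @return scalar background intensity.
#' @export
estimate_background <- function(field, mask) {
  check_same_shape(field, mask)
  bg <- field$pixels[mask$labels == 0L]
  if (length(bg) == 0L)
    stop("estimate_background(): mask has no background pixels")
  stats::median(as.numeric(bg))
}

#' Extract per-cell pixel records from a field + mask pair
#'
#' One record per label 1..K whose area is at least `min_area`; smaller
#' cells are dropped and reported via message and the `"dropped"`
#' attribute. Records carry the field-level background estimate so that
#' scoring can subtract it.
#'
#' @param field a `fluorescence_field`.
#' @param mask matching `label_mask`.
#' @param chip_id,well_id,population_id identifiers copied onto each record.
#' @param min_area minimum cell area in pixels (default 200).
#' @return list of `cell_record` objects: `cell_id`, identifiers,
#'   `intensities` (numeric vector), `area_px`, `background_estimate`,
#'   `touches_border` flag.
#' @export
extract_cells <- function(field, mask, chip_id = "chip1", well_id = "w1",
                          population_id = "pop", min_area = 200L) {
  check_same_shape(field, mask)
  k <- mask$n_cells
  if (k == 0L) return(list())
  bg <- estimate_background(field, mask)
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  records <- vector("list", k)
  dropped <- character(0)
  for (id in seq_len(k)) {
    idx <- which(lab == id)
    rec <- structure(list(
      cell_id = id, chip_id = chip_id, well_id = well_id,
      population_id = population_id,
      intensities = as.numeric(field$pixels[idx]),
      area_px = length(idx), background_estimate = bg,
      touches_border = id %in% border), class = "cell_record")
    if (length(idx) < min_area) {
      dropped <- c(dropped, sprintf("cell %d: area %d < min_area %d",
                                    id, length(idx), as.integer(min_area)))
      attr(rec, "dropped") <- TRUE
      records[[id]] <- NULL
      next
    }
    records[[id]] <- rec
  }
  if (length(dropped))
    message("extract_cells(): dropped ", length(dropped), " cell(s): ",
            paste(dropped, collapse = "; "))
  out <- records[!vapply(records, is.null, logical(1))]
  attr(out, "dropped") <- dropped
  out
}

#' Automatic cell segmentation for unattended runs
#'
#' The assay's reference analysis outlines cells by hand; this automatic
#' path exists so synthetic fixtures can run unattended. Pipeline:
#' Gaussian smoothing, Otsu threshold, hole filling, connected components,
#' and an optional watershed split of touching cells. The result satisfies
#' the gapless 1..K label-mask contract.
#'
#' @param field a `fluorescence_field`.
#' @param bright_field optional matching bright-field image (currently
#'   combined additively with the fluorescence channel before smoothing).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param watershed split touching objects with a distance-map watershed.
#' @param min_area discard components smaller than this before labeling.
#' @return a `label_mask` (K = 0 with a warning when no foreground found).
#' @export
segment_cells <- function(field, bright_field = NULL, smooth_sigma = 3,
                          watershed = FALSE, min_area = 50L) {
  px <- field$pixels
  if (!is.null(bright_field)) {
    check_same_shape(field, list(labels = bright_field$pixels))
    px <- px + bright_field$pixels
  }
  if (diff(range(px)) == 0) {
    warning("segment_cells(): empty foreground (zero-contrast field)")
    return(label_mask(matrix(0L, nrow(px), ncol(px))))
  }
  img <- px / max(px, 1)
  sm <- EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  fg <- EBImage::fillHull(sm > thr)
  if (sum(fg) == 0) {
    warning("segment_cells(): empty foreground")
    return(label_mask(matrix(0L, nrow(px), ncol(px))))
  }
  if (watershed) {
    dm <- EBImage::distmap(fg)
    lab <- EBImage::watershed(dm, tolerance = 1)
  } else {
    lab <- EBImage::bwlabel(fg)
  }
  lab <- EBImage::imageData(lab)
  # drop specks, then relabel to a gapless 1..K
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  lab <- relabel_sequential(lab)
  label_mask(lab)
}

#' Relabel an integer mask to gapless ascending labels
#'
#' Maps the distinct positive labels (in increasing order) onto 1..K,
#' repairing gapped label sets so they satisfy the mask contract.
#'
#' @param labels integer matrix (possibly gapped labels).
#' @return integer matrix with labels exactly \{0\} U \{1..K\}.
#' @export
relabel_sequential <- function(labels) {
  labels <- as.matrix(labels)
  present <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(present)) out[labels == present[i]] <- i
  out
}

check_same_shape <- function(field, mask) {
  if (!identical(dim(field$pixels), dim(mask$labels)))
    stop("field and mask shapes differ: ",
         paste(dim(field$pixels), collapse = "x"), " vs ",
         paste(dim(mask$labels), collapse = "x"))
  invisible(TRUE)
}

#' Write a per-cell summary table
#'
#' TSV with one row per record: chip/well/population identifiers, cell id,
#' area, background estimate and mean raw intensity.
#'
#' @param records list of `cell_record`s.
#' @param path output TSV path.
#' @export
write_cell_table <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(chip_id = r$chip_id, well_id = r$well_id,
               population_id = r$population_id, cell_id = r$cell_id,
               area_px = r$area_px, background = r$background_estimate,
               mean_intensity = mean(r$intensities),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
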