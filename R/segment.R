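#' Split a multi-channel image into per-role single-channel images
#'
#' Lossless: each output matrix is the corresponding channel slice. The
#' nuclear and CQD channels are required for the segmentation workflow;
#' the transmitted-light (DIC) channel, when present, is passed through
#' for display only.
#'
#' @param img a [multichannel_image()].
#' @param required roles that must be present.
#' @return named list of integer matrices, one per role.
#' @export
split_channels <- function(img, required = c("nuclear", "cqd")) {
  stopifnot(inherits(img, "multichannel_image"))
  missing_roles <- setdiff(required, names(img$channels))
  if (length(missing_roles))
    stop("missing required channel role(s): ",
         paste(missing_roles, collapse = ", "))
  img$channels
}

#' Merge per-role channels back into a multi-channel image
#'
#' Inverse of [split_channels()]: `merge_channels(split_channels(x))`
#' reproduces `x` pixel for pixel.
#'
#' @param channels named list of matrices.
#' @param bit_depth 8 or 16.
#' @export
merge_channels <- function(channels, bit_depth = 16) {
  multichannel_image(channels, bit_depth = bit_depth)
}

#' Grayscale view of a single channel
#'
#' For single-channel data this is the identity on pixel values (the
#' container is normalised to a plain numeric matrix); the function exists
#' to make the workflow's grayscale-conversion step explicit and to reject
#' multi-channel input.
#'
#' @param channel a 2-D matrix (one channel).
#' @return the same values as a numeric matrix.
#' @export
to_grayscale <- function(channel) {
  if (inherits(channel, "multichannel_image"))
    stop("to_grayscale expects a single channel; use split_channels() first")
  if (!is.matrix(channel)) stop("channel must be a 2-D matrix")
  channel
}

#' Threshold a grayscale image into a binary mask
#'
#' Foreground is `pixel > threshold`. With `method = "otsu"` the threshold
#' maximises the between-class variance of the image's integer histogram
#' (computed via EBImage); with `method = "fixed"` the given value is used
#' as-is, for bit-exact reproducibility. The threshold actually applied is
#' always returned for provenance.
#'
#' @param gray numeric/integer matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold (a.u.) when `method = "fixed"`.
#' @param bit_depth histogram range for Otsu; inferred from the data
#'   (<= 255 means 8-bit) when NULL.
#' @return list with `mask` (logical matrix), `threshold`, `method`.
#' @export
threshold_mask <- function(gray, method = c("otsu", "fixed"),
                           fixed_value = NULL, bit_depth = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(gray))
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed_value required for method = 'fixed'")
    thr <- fixed_value
  } else {
    if (min(gray) == max(gray))
      stop("constant image: Otsu is undefined; use method = 'fixed' ",
           "with an explicit threshold")
    bit_depth <- bit_depth %||% (if (max(gray) <= 255) 8 else 16)
    thr <- otsu_threshold(gray, 2^bit_depth)
  }
  list(mask = gray > thr, threshold = thr, method = method)
}

# Otsu's threshold on the integer histogram via cumulative sums: the cut
# level k (mask = value > k) maximising the between-class variance over
# all possible splits; the first maximiser wins on ties.
otsu_threshold <- function(gray, levels) {
  cnt <- as.numeric(tabulate(as.integer(gray) + 1L, levels))
  lev <- as.numeric(0:(levels - 1))
  w1 <- cumsum(cnt)
  m1 <- cumsum(cnt * lev)
  total <- w1[levels]
  mtot <- m1[levels]
  k <- seq_len(levels - 1)
  w0 <- w1[k]; wb <- total - w0
  v <- ifelse(w0 > 0 & wb > 0,
              w0 * wb * (m1[k] / w0 - (mtot - m1[k]) / wb)^2, -Inf)
  lev[which.max(v)]
}

#' Nuclei seed labels from the nuclear channel
#'
#' Thresholds the nuclear (DRAQ5-like) channel, labels connected
#' components, drops components below `min_nucleus_area` and returns the
#' label image plus seed centroids. Finding zero nuclei is a warning, not
#' an error (an empty field is a legitimate image).
#'
#' @param nuclear_gray nuclear-channel matrix.
#' @param method,fixed_value,bit_depth passed to [threshold_mask()].
#' @param min_nucleus_area smallest accepted nucleus (pixels).
#' @return list with `labels` (integer matrix, compact labels 1..n),
#'   `centroids` (data.frame label/row/col/area), `threshold`.
#' @export
nuclei_seeds <- function(nuclear_gray, method = c("otsu", "fixed"),
                         fixed_value = NULL, bit_depth = NULL,
                         min_nucleus_area = 30) {
  tm <- threshold_mask(nuclear_gray, method, fixed_value, bit_depth)
  cc <- EBImage::bwlabel(EBImage::Image(tm$mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(cc)), nrow(nuclear_gray))
  if (max(lab) == 0) {
    warning("no nuclei found above threshold")
    return(list(labels = lab, centroids = empty_centroids(),
                threshold = tm$threshold))
  }
  areas <- tabulate(lab[lab > 0], max(lab))
  keep <- which(areas >= min_nucleus_area)
  if (length(keep) == 0) {
    warning("no nuclei of at least ", min_nucleus_area, " px found")
    return(list(labels = matrix(0L, nrow(lab), ncol(lab)),
                centroids = empty_centroids(), threshold = tm$threshold))
  }
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0 & remap[pmax(lab, 1)] > 0
  out[sel] <- remap[lab[sel]]
  idx <- which(out > 0, arr.ind = TRUE)
  l <- out[out > 0]
  centroids <- data.frame(
    label = seq_along(keep),
    row = as.numeric(tapply(idx[, 1], l, mean)),
    col = as.numeric(tapply(idx[, 2], l, mean)),
    area = as.integer(tabulate(l, length(keep))))
  list(labels = out, centroids = centroids, threshold = tm$threshold)
}

empty_centroids <- function() {
  data.frame(label = integer(0), row = numeric(0), col = numeric(0),
             area = integer(0))
}

#' Seed-mediated segmentation: grow every nucleus across the foreground
#'
#' Multi-source region growing on the geodesic distance within the
#' foreground mask (4-connected): every foreground pixel connected to at
#' least one seed is assigned the label of its geodesically nearest seed;
#' ties go to the smaller label, deterministically. Foreground components
#' containing no seed stay background. A seed lying entirely outside the
#' foreground keeps only its own pixels (with a warning).
#'
#' @param foreground logical matrix (cell foreground), or a
#'   [threshold_mask()] result.
#' @param seeds integer label matrix of nuclei seeds.
#' @return integer label matrix of whole cells.
#' @export
seeded_segmentation <- function(foreground, seeds) {
  if (is.list(foreground) && !is.null(foreground$mask))
    foreground <- foreground$mask
  stopifnot(is.matrix(foreground), is.matrix(seeds))
  if (!identical(dim(foreground), dim(seeds)))
    stop("foreground and seeds must have identical dimensions")
  storage.mode(seeds) <- "integer"
  labs <- sort(unique(seeds[seeds > 0]))
  for (l in labs) {
    if (!any(foreground[seeds == l]))
      warning("seed ", l, " lies entirely outside the foreground; ",
              "it keeps only its own pixels")
  }
  seeded_growth_cpp(seeds, foreground)
}

#' Cytoplasm-only labels by mask subtraction
#'
#' Per-cell set difference: a pixel keeps its cell label iff it belongs to
#' a segmented cell AND is not a nucleus pixel AND is foreground — "cells
#' without nuclei". This normalised contract is insensitive to the order
#' in which the nuclei and background masks are subtracted.
#'
#' @param cells integer label matrix of whole cells
#'   ([seeded_segmentation()] output).
#' @param nuclei logical matrix (or nuclei label matrix) marking nucleus
#'   pixels.
#' @param foreground logical matrix of cell foreground (the background
#'   mask's complement).
#' @return integer label matrix of cytoplasm-only objects.
#' @export
cytoplasm_labels <- function(cells, nuclei, foreground) {
  if (is.list(nuclei) && !is.null(nuclei$labels)) nuclei <- nuclei$labels
  if (is.list(foreground) && !is.null(foreground$mask))
    foreground <- foreground$mask
  nuc <- if (is.logical(nuclei)) nuclei else nuclei > 0
  if (!identical(dim(cells), dim(nuc)) ||
      !identical(dim(cells), dim(foreground)))
    stop("cells, nuclei and foreground must have identical dimensions")
  out <- cells
  out[nuc | !foreground] <- 0L
  storage.mode(out) <- "integer"
  out
}

#' Full single-image segmentation workflow
#'
#' The end-to-end per-image chain: split channels, grayscale the CQD
#' channel, threshold it (background mask), threshold + label the nuclear
#' channel (seeds), grow seeds over the cell foreground (the union of the
#' CQD-positive mask and the nuclei, since the cytosolic dots are dark
#' over the nucleus), and subtract masks to get cytoplasm-only labels.
#'
#' @param img a [multichannel_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_cqd,fixed_nuclear fixed thresholds when
#'   `threshold_method = "fixed"`.
#' @param min_nucleus_area,min_cytoplasm_area size filters (pixels).
#' @param exclude_border drop cells touching the image border.
#' @return list with `cyto_labels`, `cell_labels`, `nuclei` (seed result),
#'   `cqd_gray`, `cqd_mask`, `params` (thresholds and filters echoed for
#'   provenance).
#' @export
segment_image <- function(img, threshold_method = c("otsu", "fixed"),
                          fixed_cqd = NULL, fixed_nuclear = NULL,
                          min_nucleus_area = 30, min_cytoplasm_area = 100,
                          exclude_border = FALSE) {
  threshold_method <- match.arg(threshold_method)
  ch <- split_channels(img)
  cqd_gray <- to_grayscale(ch$cqd)
  bit <- img$bit_depth
  cqd_mask <- threshold_mask(cqd_gray, threshold_method, fixed_cqd, bit)
  nuc <- nuclei_seeds(ch$nuclear, threshold_method, fixed_nuclear, bit,
                      min_nucleus_area)
  cellfg <- cqd_mask$mask | nuc$labels > 0
  cells <- seeded_segmentation(cellfg, nuc$labels)
  cyto <- cytoplasm_labels(cells, nuc$labels, cqd_mask$mask)
  if (exclude_border) {
    border_labels <- unique(c(cyto[1, ], cyto[nrow(cyto), ],
                              cyto[, 1], cyto[, ncol(cyto)],
                              cells[1, ], cells[nrow(cells), ],
                              cells[, 1], cells[, ncol(cells)]))
    border_labels <- border_labels[border_labels > 0]
    cyto[cyto %in% border_labels] <- 0L
  }
  list(cyto_labels = cyto, cell_labels = cells, nuclei = nuc,
       cqd_gray = cqd_gray, cqd_mask = cqd_mask,
       params = list(threshold_method = threshold_method,
                     cqd_threshold = cqd_mask$threshold,
                     nuclear_threshold = nuc$threshold,
                     min_nucleus_area = min_nucleus_area,
                     min_cytoplasm_area = min_cytoplasm_area,
                     exclude_border = exclude_border))
}
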