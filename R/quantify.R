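#' Per-object area and mean intensity
#'
#' One record per label with area >= `min_area`; the mean is the
#' arithmetic mean of the intensity image over the label's pixels. Raw
#' means are reported (no background subtraction) so groups acquired
#' under identical settings are directly comparable; set
#' `subtract_background` to remove the image's background median for
#' users who want offset-free values.
#'
#' @param labels integer label matrix (cytoplasm-only objects).
#' @param intensity grayscale matrix, same shape.
#' @param min_area smallest reported object (pixels).
#' @param subtract_background subtract the median intensity of
#'   unlabelled pixels from every mean.
#' @return data.frame with `cell_id`, `area`, `mean_intensity`, ordered
#'   by `cell_id`.
#' @export
measure_objects <- function(labels, intensity, min_area = 0,
                            subtract_background = FALSE) {
  stopifnot(is.matrix(labels), is.matrix(intensity))
  if (!identical(dim(labels), dim(intensity)))
    stop("labels and intensity must have identical dimensions")
  storage.mode(labels) <- "integer"
  if (max(labels) == 0)
    return(data.frame(cell_id = integer(0), area = numeric(0),
                      mean_intensity = numeric(0)))
  st <- label_stats_cpp(labels, intensity + 0.0)
  keep <- st$area >= max(min_area, 1)
  out <- data.frame(cell_id = st$label[keep], area = st$area[keep],
                    mean_intensity = st$sum[keep] / st$area[keep])
  if (subtract_background) {
    bg <- stats::median(intensity[labels == 0])
    out$mean_intensity <- out$mean_intensity - bg
  }
  out[order(out$cell_id), , drop = FALSE]
}

#' Pool per-cell records across the images of one experimental group
#'
#' Concatenates per-cell mean intensities from one or more images into a
#' single group sample, keeping image provenance. Records measured under
#' different parameter sets (thresholds, size filters) must not be pooled
#' under one group name; a `params` attribute mismatch is an error.
#'
#' @param records named list of [measure_objects()] data.frames, names
#'   are image ids (a single unnamed data.frame is accepted).
#' @param group group name stamped on every row.
#' @return data.frame with `image_id`, `cell_id`, `area`,
#'   `mean_intensity`, `group`, ordered by (image_id, cell_id).
#' @export
pool_group <- function(records, group) {
  if (is.data.frame(records)) records <- list(image1 = records)
  if (length(records) == 0) stop("no records to pool")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    names(records) <- sprintf("image%d", seq_along(records))
  pars <- lapply(records, attr, "params")
  pars <- pars[!vapply(pars, is.null, logical(1))]
  if (length(pars) > 1 &&
      !all(vapply(pars, identical, logical(1), pars[[1]])))
    stop("cannot pool group '", group,
         "': images were measured under different parameter sets")
  out <- do.call(rbind, lapply(names(records), function(id) {
    r <- records[[id]]
    if (nrow(r) == 0) return(NULL)
    data.frame(image_id = id, r, group = group, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(image_id = character(0), cell_id = integer(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      group = character(0)))
  out <- out[order(out$image_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match segmented labels to ground-truth cell ids
#'
#' Segmentation labels follow connected-component scan order, not the
#' generator's placement order; this maps each segmented cell to the
#' ground-truth cell whose nucleus contains the seed centroid.
#'
#' @param seg a [segment_image()] result.
#' @param field the [generate_cell_field()] ground truth for the same
#'   scene.
#' @return integer vector: `truth_id[label]` is the truth `cell_id` for
#'   segmented label `label` (NA where no nucleus matches).
#' @export
match_labels_to_truth <- function(seg, field) {
  cen <- seg$nuclei$centroids
  if (nrow(cen) == 0) return(integer(0))
  ids <- vapply(seq_len(nrow(cen)), function(i) {
    r <- as.integer(round(cen$row[i])); c <- as.integer(round(cen$col[i]))
    id <- field$nuc_labels[r, c]
    if (id > 0) id else NA_integer_
  }, integer(1))
  ids
}
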