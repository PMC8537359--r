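#' Write / read a multi-channel image as a multi-page TIFF
#'
#' One page per channel, written in the order of `img$channels`. TIFF
#' carries no channel-role metadata, so the roles must be supplied again
#' on read (defaults match the writer's order for scenes produced by
#' [write_scene()]: nuclear, cqd, then dic when present).
#'
#' @param img a [multichannel_image()].
#' @param path TIFF file path.
#' @return the path (write) or a [multichannel_image()] (read), invisibly.
#' @export
write_multichannel_tiff <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  full <- 2^img$bit_depth - 1
  pages <- lapply(img$channels, function(ch) ch / full)
  tiff::writeTIFF(pages, path, bits.per.sample = img$bit_depth)
  invisible(path)
}

#' @rdname write_multichannel_tiff
#' @param roles channel roles, in page order.
#' @param bit_depth bit depth used when the file was written.
#' @export
read_multichannel_tiff <- function(path, roles = c("nuclear", "cqd"),
                                   bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(roles))
    stop("TIFF has ", length(pages), " pages but ", length(roles),
         " roles were requested")
  full <- 2^bit_depth - 1
  channels <- lapply(pages[seq_along(roles)], function(p) {
    matrix(as.integer(round(p * full)), nrow(p))
  })
  names(channels) <- roles
  multichannel_image(channels, bit_depth = bit_depth)
}
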