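#' Geometry parameters for the synthetic cell field
#'
#' Cells are ellipses with a concentric, co-oriented elliptical nucleus —
#' a deliberate simplification of real adherent-cell outlines that is
#' sufficient for exercising mask arithmetic and seeded segmentation.
#' Non-overlap is enforced by rejection sampling on bounding circles, with
#' at least `min_gap` pixels of background between any two cells so that
#' every foreground component contains at most one nucleus seed.
#'
#' @param cyto_axis_range range (pixels) for the cytoplasm semi-major axis.
#' @param axis_ratio_range range for the minor/major axis ratio.
#' @param nuc_frac_range range for the nucleus/cytoplasm axis fraction.
#' @param min_gap minimum background gap (pixels) between cell boundaries.
#' @param max_tries_per_cell rejection-sampling budget per cell before the
#'   generator gives up with a density error.
#' @return list of geometry parameters.
#' @export
geometry_params <- function(cyto_axis_range = c(22, 32),
                            axis_ratio_range = c(0.7, 1),
                            nuc_frac_range = c(0.35, 0.5),
                            min_gap = 2,
                            max_tries_per_cell = 200) {
  stopifnot(length(cyto_axis_range) == 2, cyto_axis_range[1] > 0,
            diff(cyto_axis_range) >= 0,
            axis_ratio_range[1] > 0, axis_ratio_range[2] <= 1,
            nuc_frac_range[1] > 0, nuc_frac_range[2] < 1,
            min_gap >= 1, max_tries_per_cell >= 1)
  list(cyto_axis_range = cyto_axis_range,
       axis_ratio_range = axis_ratio_range,
       nuc_frac_range = nuc_frac_range,
       min_gap = min_gap,
       max_tries_per_cell = max_tries_per_cell)
}

#' Intensity parameters for the synthetic channels
#'
#' Defaults emulate a 16-bit confocal acquisition: the CQD (blue, 405 nm
#' line) cytoplasmic signal sits at ~30% of full scale before quenching and
#' the DRAQ5-like nuclear (far-red, 633 nm line) signal at ~70%. Per-cell
#' CQD brightness is jittered by a relative Gaussian factor
#' (`base_jitter_sd`) to mimic cell-to-cell loading variability.
#'
#' @param base_cqd mean unquenched cytoplasmic CQD intensity (a.u.).
#' @param base_jitter_sd relative s.d. of per-cell brightness jitter.
#' @param nuc_intensity nuclear-channel intensity inside nuclei (a.u.).
#' @param bit_depth 8 or 16.
#' @return list of intensity parameters.
#' @export
intensity_params <- function(base_cqd = 20000, base_jitter_sd = 0.05,
                             nuc_intensity = 45000, bit_depth = 16) {
  stopifnot(bit_depth %in% c(8, 16), base_cqd > 0, base_jitter_sd >= 0,
            nuc_intensity > 0)
  full <- 2^bit_depth - 1
  if (base_cqd > full || nuc_intensity > full)
    stop("intensities exceed bit-depth range")
  list(base_cqd = base_cqd, base_jitter_sd = base_jitter_sd,
       nuc_intensity = nuc_intensity, bit_depth = bit_depth)
}

# Pixel-centre membership of a rotated ellipse, vectorised over coordinates.
ellipse_member <- function(rows, cols, cr, cc, a, b, theta) {
  dy <- rows - cr
  dx <- cols - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Paint an ellipse into an integer label matrix (bounding-box restricted).
paint_ellipse <- function(labels, cr, cc, a, b, theta, value) {
  r0 <- max(1L, floor(cr - max(a, b))); r1 <- min(nrow(labels), ceiling(cr + max(a, b)))
  c0 <- max(1L, floor(cc - max(a, b))); c1 <- min(ncol(labels), ceiling(cc + max(a, b)))
  rows <- r0:r1; cols <- c0:c1
  rg <- matrix(rows, length(rows), length(cols))
  cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- ellipse_member(rg, cg, cr, cc, a, b, theta)
  sub <- labels[rows, cols, drop = FALSE]
  sub[inside] <- value
  labels[rows, cols] <- sub
  labels
}

#' Generate a field of non-overlapping synthetic cells with ground truth
#'
#' Places `n_cells` elliptical cells (each with one concentric elliptical
#' nucleus) uniformly at random in the image, rejecting placements whose
#' bounding circles come within `min_gap` pixels of an existing cell, and
#' rasterises cytoplasm and nucleus label images (pixel-centre sampling).
#' The returned ground truth records geometry, per-cell unquenched CQD
#' brightness, the quench factor and the group label, so downstream
#' segmentation and quantification can be validated pixel-by-pixel.
#'
#' @param n_cells number of cells (>= 0).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param geometry see [geometry_params()].
#' @param intensity see [intensity_params()].
#' @param quench_factor quench factor q in (0, 1]; scalar or length
#'   `n_cells`. q = 1 means unquenched (no cytosolic cytochrome c).
#' @param group group label stored with every cell.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return object of class `cell_field`: list with `truth` (one row per
#'   cell), `cyto_labels` and `nuc_labels` (integer matrices; cytoplasm
#'   labels exclude the nucleus), `shape`, `intensity` and `geometry`.
#' @export
generate_cell_field <- function(n_cells,
                                image_shape = c(512L, 512L),
                                geometry = geometry_params(),
                                intensity = intensity_params(),
                                quench_factor = 1,
                                group = "control",
                                seed = NULL) {
  stopifnot(n_cells >= 0, length(image_shape) == 2, all(image_shape >= 8))
  if (any(quench_factor < 0 | quench_factor > 1))
    stop("quench_factor must lie in [0, 1]")
  q <- rep_len(quench_factor, max(n_cells, 1))
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  max_ax <- geometry$cyto_axis_range[2]
  if (n_cells > 0 && (nr < 2 * max_ax + 4 || nc < 2 * max_ax + 4))
    stop("image_shape too small for the requested cell geometry")

  cyto <- matrix(0L, nr, nc)
  nuc <- matrix(0L, nr, nc)
  if (n_cells == 0) {
    truth <- empty_truth()
    return(new_cell_field(truth, cyto, nuc, c(nr, nc), intensity, geometry))
  }

  with_seed(seed, {
    placed <- data.frame(cr = numeric(0), cc = numeric(0), R = numeric(0))
    rows <- list()
    budget <- geometry$max_tries_per_cell * n_cells
    tries <- 0L
    for (i in seq_len(n_cells)) {
      repeat {
        tries <- tries + 1L
        if (tries > budget)
          stop(sprintf(paste0(
            "could not place %d cells of max radius %.0f px in a %dx%d image ",
            "after %d tries: cell density too high for non-overlapping ",
            "placement; reduce n_cells or cyto_axis_range"),
            n_cells, max_ax, nr, nc, budget))
        a <- runif(1, geometry$cyto_axis_range[1], geometry$cyto_axis_range[2])
        b <- a * runif(1, geometry$axis_ratio_range[1], geometry$axis_ratio_range[2])
        theta <- runif(1, 0, pi)
        R <- max(a, b)
        cr <- runif(1, R + 2, nr - R - 1)
        cc <- runif(1, R + 2, nc - R - 1)
        if (nrow(placed) == 0 ||
            all(sqrt((placed$cr - cr)^2 + (placed$cc - cc)^2) >=
                placed$R + R + geometry$min_gap)) break
      }
      placed <- rbind(placed, data.frame(cr = cr, cc = cc, R = R))
      nf <- runif(1, geometry$nuc_frac_range[1], geometry$nuc_frac_range[2])
      jit <- max(0.5, 1 + rnorm(1, 0, intensity$base_jitter_sd))
      rows[[i]] <- data.frame(
        cell_id = i, center_row = cr, center_col = cc,
        cyto_a = a, cyto_b = b, theta = theta,
        nuc_a = a * nf, nuc_b = b * nf,
        base_cqd_intensity = intensity$base_cqd * jit,
        quench_factor = q[i],
        nuc_intensity = intensity$nuc_intensity,
        group = group, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    for (i in seq_len(n_cells)) {
      tr <- truth[i, ]
      if (tr$nuc_a >= tr$cyto_a || tr$nuc_b >= tr$cyto_b)
        stop("nucleus axes must be strictly smaller than cytoplasm axes")
      cyto <- paint_ellipse(cyto, tr$center_row, tr$center_col,
                            tr$cyto_a, tr$cyto_b, tr$theta, i)
      nuc <- paint_ellipse(nuc, tr$center_row, tr$center_col,
                           tr$nuc_a, tr$nuc_b, tr$theta, i)
    }
    cyto[nuc > 0] <- 0L   # cytoplasm labels exclude the nucleus
    new_cell_field(truth, cyto, nuc, c(nr, nc), intensity, geometry)
  })
}

empty_truth <- function() {
  data.frame(cell_id = integer(0), center_row = numeric(0),
             center_col = numeric(0), cyto_a = numeric(0), cyto_b = numeric(0),
             theta = numeric(0), nuc_a = numeric(0), nuc_b = numeric(0),
             base_cqd_intensity = numeric(0), quench_factor = numeric(0),
             nuc_intensity = numeric(0), group = character(0),
             stringsAsFactors = FALSE)
}

new_cell_field <- function(truth, cyto, nuc, shape, intensity, geometry) {
  structure(list(truth = truth, cyto_labels = cyto, nuc_labels = nuc,
                 shape = as.integer(shape), intensity = intensity,
                 geometry = geometry),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("cell_field: %d cells in %dx%d px (group %s)\n",
              nrow(x$truth), x$shape[1], x$shape[2],
              paste(unique(x$truth$group), collapse = ",")))
  invisible(x)
}

#' Multi-channel image container
#'
#' @param channels named list of integer matrices; names are channel roles
#'   among `"nuclear"`, `"cqd"`, `"dic"`. All channels must share shape.
#' @param bit_depth 8 or 16; all pixel values must fit the range.
#' @return object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, bit_depth = 16) {
  stopifnot(is.list(channels), length(channels) >= 1, bit_depth %in% c(8, 16))
  roles <- names(channels)
  if (is.null(roles) || any(!nzchar(roles)))
    stop("channels must be a named list (roles: nuclear, cqd, dic)")
  if (!all(roles %in% c("nuclear", "cqd", "dic")))
    stop("unknown channel role(s): ",
         paste(setdiff(roles, c("nuclear", "cqd", "dic")), collapse = ", "))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same shape")
  full <- 2^bit_depth - 1
  for (ch in channels)
    if (min(ch) < 0 || max(ch) > full)
      stop("pixel values outside bit-depth range")
  structure(list(channels = channels, bit_depth = bit_depth),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("multichannel_image: %dx%d px, %d-bit, channels: %s\n",
              d[1], d[2], x$bit_depth, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Render a synthetic cell field into a multi-channel confocal image
#'
#' The CQD channel carries `background_level` everywhere plus
#' `base_cqd_intensity * quench_factor` over each cell's cytoplasm (the
#' nucleus carries background only: the dots are cytosolic). The nuclear
#' channel carries `nuc_intensity` inside nuclei. Additive Gaussian read
#' noise is applied per pixel, then values are rounded and clipped to the
#' bit depth. With `gaussian_sd = 0` the render is exactly the expectation,
#' so ground-truth quench factors are recoverable without error.
#'
#' @param field a [generate_cell_field()] result.
#' @param background_level background offset (a.u.); default 2% of full
#'   scale, the typical detector offset of a confocal acquisition.
#' @param gaussian_sd additive noise s.d. (a.u.); default 5% of the mean
#'   unquenched CQD signal.
#' @param include_dic also render a flat transmitted-light channel with a
#'   mild darkening over cells (display only, never quantified).
#' @param seed RNG seed.
#' @return a [multichannel_image()].
#' @export
render_channels <- function(field, background_level = NULL, gaussian_sd = NULL,
                            include_dic = FALSE, seed = NULL) {
  stopifnot(inherits(field, "cell_field"))
  bit <- field$intensity$bit_depth
  full <- 2^bit - 1
  background_level <- background_level %||% round(0.02 * full)
  gaussian_sd <- gaussian_sd %||% (0.05 * field$intensity$base_cqd)
  if (background_level < 0 || gaussian_sd < 0)
    stop("noise parameters must be non-negative")

  nr <- field$shape[1]; nc <- field$shape[2]
  cqd <- matrix(background_level, nr, nc)
  nucch <- matrix(background_level, nr, nc)
  tr <- field$truth
  if (nrow(tr) > 0) {
    amp <- tr$base_cqd_intensity * tr$quench_factor
    cm <- field$cyto_labels
    sel <- cm > 0
    cqd[sel] <- cqd[sel] + amp[cm[sel]]
    nm <- field$nuc_labels
    seln <- nm > 0
    nucch[seln] <- nucch[seln] + tr$nuc_intensity[nm[seln]]
  }
  channels <- list(nuclear = nucch, cqd = cqd)
  if (include_dic) {
    dic <- matrix(0.5 * full, nr, nc)
    dic[field$cyto_labels > 0 | field$nuc_labels > 0] <- 0.45 * full
    channels$dic <- dic
  }
  with_seed(seed, {
    channels <- lapply(channels, function(ch) {
      if (gaussian_sd > 0)
        ch <- ch + matrix(rnorm(length(ch), 0, gaussian_sd), nrow(ch))
      matrix(as.integer(pmin(pmax(round(ch), 0), full)), nrow(ch))
    })
    multichannel_image(channels, bit_depth = bit)
  })
}

#' Quench calibration: relative CQD intensity vs cytochrome c concentration
#'
#' The functional form linking cytosolic cytochrome c concentration to CQD
#' emission is not fixed by theory here; the calibration is a pluggable
#' monotone model. Two forms are offered: Stern-Volmer, I0/I = 1 + K c
#' (so q(c) = 1/(1 + K c)), and an inner-filter-effect style exponential,
#' q(c) = 10^(-k c). The default Stern-Volmer constant K = 0.04 per µM puts
#' q(25 µM) = 0.5.
#'
#' @param model `"stern_volmer"` or `"ife_exponential"`.
#' @param K Stern-Volmer constant (per µM).
#' @param k IFE exponential coefficient (per µM).
#' @return object of class `quench_calibration`.
#' @export
quench_calibration <- function(model = c("stern_volmer", "ife_exponential"),
                               K = 0.04, k = 0.012) {
  model <- match.arg(model)
  params <- switch(model,
                   stern_volmer = {
                     stopifnot(K >= 0); c(K = K)
                   },
                   ife_exponential = {
                     stopifnot(k >= 0); c(k = k)
                   })
  structure(list(model = model, params = params,
                 concentration = NULL, rel_intensity = NULL,
                 residuals = NULL),
            class = "quench_calibration")
}

#' Quench factor from cytochrome c concentration
#'
#' Evaluates the calibration's monotone quench curve: the fraction of the
#' unquenched CQD emission remaining at cytosolic concentration `c_um`.
#' Always 1 at c = 0 and non-increasing in c.
#'
#' @param c_um concentration(s), µM; must be >= 0.
#' @param calibration a [quench_calibration()].
#' @return quench factor(s) in (0, 1].
#' @export
quench_factor_from_concentration <- function(c_um,
                                             calibration = quench_calibration()) {
  stopifnot(inherits(calibration, "quench_calibration"))
  if (any(c_um < 0)) stop("concentration must be non-negative")
  switch(calibration$model,
         stern_volmer = 1 / (1 + calibration$params[["K"]] * c_um),
         ife_exponential = 10^(-calibration$params[["k"]] * c_um))
}

#' Generate a Gaussian emission/absorbance spectrum on a wavelength grid
#'
#' Emulates a single-band fluorescence spectrum (e.g. the CQDs' blue
#' emission peaking at 440 nm under 360 nm excitation) as a Gaussian of
#' given centre, width and amplitude sampled on a wavelength grid.
#'
#' @param peak_nm peak wavelength (nm).
#' @param width_nm Gaussian sigma (nm), > 0.
#' @param amplitude peak amplitude (a.u.), >= 0.
#' @param grid wavelength grid (nm), strictly increasing.
#' @return a [spectrum_trace()].
#' @export
generate_spectrum <- function(peak_nm, width_nm, amplitude = 1,
                              grid = seq(370, 800, by = 1)) {
  if (length(grid) == 0) stop("wavelength grid must be non-empty")
  if (width_nm <= 0) stop("width_nm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  spectrum_trace(grid, amplitude * exp(-(grid - peak_nm)^2 / (2 * width_nm^2)))
}

#' Write a rendered scene to disk (TIFF + ground-truth CSV + config JSON)
#'
#' Writes a multi-page TIFF (one page per channel, in the order of
#' `img$channels`), the ground truth as CSV (one row per cell) and a JSON
#' sidecar recording channel order, bit depth and generation parameters.
#'
#' @param field a [generate_cell_field()] result.
#' @param img the matching [render_channels()] output.
#' @param path output path without extension; `.tif`, `_truth.csv` and
#'   `_scene.json` are appended.
#' @param params extra generation parameters echoed into the JSON sidecar.
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(field, img, path, params = list()) {
  tif <- paste0(path, ".tif")
  csv <- paste0(path, "_truth.csv")
  js <- paste0(path, "_scene.json")
  write_multichannel_tiff(img, tif)
  write.csv(field$truth, csv, row.names = FALSE)
  jsonlite::write_json(
    list(channels = names(img$channels), bit_depth = img$bit_depth,
         shape = field$shape, n_cells = nrow(field$truth), params = params),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tif, truth = csv, json = js))
}
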