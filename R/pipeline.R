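#' Default run configuration
#'
#' The default emulates the study design: five groups (control and two
#' doses each of etoposide and staurosporine), three 1024x1024 16-bit
#' images of ~50 cells per group, one shared render/threshold parameter
#' set across all groups (the in-silico analogue of acquiring every
#' sample under identical settings), and a Stern-Volmer quench
#' calibration with K = 0.04 per µM. Per-group cytosolic cytochrome c
#' concentrations are scenario defaults in the low-µM range.
#'
#' @param seed RNG seed (mandatory for every run).
#' @param output_dir where artifacts are written.
#' @param n_images,n_cells per-group image count and cells per image.
#' @param image_shape image size in pixels.
#' @return config list suitable for [validate_config()] / [run_pipeline()].
#' @export
default_run_config <- function(seed, output_dir = tempfile("cq_run_"),
                               n_images = 3, n_cells = 50,
                               image_shape = c(1024L, 1024L)) {
  list(
    seed = seed,
    output_dir = output_dir,
    image_shape = image_shape,
    groups = list(
      list(name = "control", control = TRUE, n_images = n_images,
           n_cells = n_cells, cytc_um = 0),
      list(name = "ETO25", n_images = n_images, n_cells = n_cells,
           cytc_um = 5),
      list(name = "ETO50", n_images = n_images, n_cells = n_cells,
           cytc_um = 15),
      list(name = "STAU25", n_images = n_images, n_cells = n_cells,
           cytc_um = 10),
      list(name = "STAU50", n_images = n_images, n_cells = n_cells,
           cytc_um = 25)),
    calibration = list(model = "stern_volmer", K = 0.04),
    noise = list(background_level = NULL, gaussian_sd = NULL),
    geometry = list(), intensity = list(),
    threshold = list(method = "otsu", fixed_cqd = NULL, fixed_nuclear = NULL),
    min_nucleus_area = 30, min_cytoplasm_area = 100,
    exclude_border = FALSE,
    stats = list(alpha = 0.05, n_bins = 30, ks_nsim = 10000,
                 ks_null_seed = 104729, var_equal = FALSE,
                 bonferroni = FALSE))
}

#' Validate and normalise a run configuration
#'
#' Checks every invariant (mandatory seed, exactly one control group,
#' unique group names, each group giving either a cytochrome c
#' concentration or an explicit quench factor, valid parameter ranges),
#' fills omitted sections with defaults, and aggregates ALL violations
#' into one error message instead of failing on the first.
#'
#' @param raw a config list (e.g. from [yaml::read_yaml()]).
#' @return the normalised config (class `run_config`), or an error
#'   listing every problem found.
#' @export
validate_config <- function(raw) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!is.list(raw)) stop("config must be a list")

  if (is.null(raw$seed)) add("seed is mandatory")
  else if (!is.numeric(raw$seed) || length(raw$seed) != 1 ||
           raw$seed != round(raw$seed)) add("seed must be a single integer")
  if (is.null(raw$output_dir)) add("output_dir is mandatory")

  shape <- raw$image_shape %||% c(1024L, 1024L)
  if (length(shape) != 2 || any(shape < 64))
    add("image_shape must be two values >= 64")

  groups <- raw$groups
  if (is.null(groups) || length(groups) == 0) {
    add("at least one group is required")
  } else {
    nms <- vapply(groups, function(g) g$name %||% NA_character_, character(1))
    if (anyNA(nms)) add("every group needs a name")
    if (anyDuplicated(nms)) add("group names must be unique")
    is_ctrl <- vapply(groups, function(g) isTRUE(g$control), logical(1))
    if (sum(is_ctrl) != 1)
      add(sprintf("exactly one group must be flagged control (found %d)",
                  sum(is_ctrl)))
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      has_c <- !is.null(g$cytc_um)
      has_q <- !is.null(g$quench_factor)
      if (!has_c && !has_q)
        add(sprintf("group '%s': give cytc_um or quench_factor",
                    g$name %||% i))
      if (has_c && g$cytc_um < 0)
        add(sprintf("group '%s': cytc_um must be >= 0", g$name))
      if (has_q && (g$quench_factor <= 0 || g$quench_factor > 1))
        add(sprintf("group '%s': quench_factor must be in (0, 1]", g$name))
      if ((g$n_images %||% 3) < 1)
        add(sprintf("group '%s': n_images must be >= 1", g$name))
      if ((g$n_cells %||% 50) < 1)
        add(sprintf("group '%s': n_cells must be >= 1", g$name))
    }
  }

  calib <- raw$calibration %||% list(model = "stern_volmer", K = 0.04)
  if (!(calib$model %||% "stern_volmer") %in%
      c("stern_volmer", "ife_exponential"))
    add("calibration model must be stern_volmer or ife_exponential")

  noise <- raw$noise %||% list()
  for (nm in c("background_level", "gaussian_sd"))
    if (!is.null(noise[[nm]]) && noise[[nm]] < 0)
      add(paste(nm, "must be >= 0"))

  thr <- raw$threshold %||% list(method = "otsu")
  if (!(thr$method %||% "otsu") %in% c("otsu", "fixed"))
    add("threshold method must be otsu or fixed")
  if ((thr$method %||% "otsu") == "fixed" &&
      (is.null(thr$fixed_cqd) || is.null(thr$fixed_nuclear)))
    add("fixed thresholding needs fixed_cqd and fixed_nuclear")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  defaults <- default_run_config(raw$seed, raw$output_dir)
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  cfg$groups <- lapply(raw$groups, function(g) {
    utils::modifyList(list(control = FALSE, n_images = 3, n_cells = 50), g,
                      keep.null = TRUE)
  })
  cfg$image_shape <- as.integer(shape)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

# full-precision CSV writer so a stats re-run from disk is bit-identical
write_records_csv <- function(records, path) {
  out <- records
  out$mean_intensity <- sprintf("%.17g", out$mean_intensity)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline: simulate, segment, quantify, compare
#'
#' For every group and image: generate a synthetic cell field (quench
#' factor from the group's cytochrome c concentration through the
#' calibration, or given explicitly), render the two channels under the
#' single shared noise model, segment (shared threshold parameter set
#' across all groups), and measure every cytoplasm object. Per-cell
#' records are pooled per group and compared against control. All
#' artifacts (TIFFs, truth CSVs, per-group records, the comparison
#' table, histogram data, resolved config, manifest with content hashes)
#' land in `config$output_dir`; identical configs give identical
#' manifests. An output directory holding a previous run with a
#' different configuration hash is refused.
#'
#' @param config a [validate_config()] result (a raw list is validated
#'   first).
#' @param write_images also write the rendered TIFFs and ground-truth
#'   CSVs (disable to keep only measurements and statistics).
#' @return the manifest: config hash, per-group summaries, the
#'   comparison table, and every written file with its MD5.
#' @export
run_pipeline <- function(config, write_images = TRUE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (!identical(prev$config_hash, hash))
      stop("output_dir contains a run with a different configuration ",
           "(hash ", prev$config_hash, " != ", hash, "); ",
           "use a fresh directory or the original config")
  }

  calib <- quench_calibration(config$calibration$model,
                              K = config$calibration$K %||% 0.04,
                              k = config$calibration$k %||% 0.012)
  geom <- do.call(geometry_params, config$geometry)
  inten <- do.call(intensity_params, config$intensity)
  files <- character(0)
  pooled <- list()
  truth_all <- list()

  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    q <- if (!is.null(g$quench_factor)) g$quench_factor
         else quench_factor_from_concentration(g$cytc_um, calib)
    recs <- list()
    for (j in seq_len(g$n_images)) {
      img_seed <- (config$seed + 7919L * gi + 101L * j) %% .Machine$integer.max
      field <- generate_cell_field(
        g$n_cells, config$image_shape, geom, inten,
        quench_factor = q, group = g$name, seed = img_seed)
      img <- render_channels(field,
                             background_level = config$noise$background_level,
                             gaussian_sd = config$noise$gaussian_sd,
                             seed = img_seed + 1L)
      image_id <- sprintf("%s_img%02d", g$name, j)
      if (write_images) {
        paths <- write_scene(field, img,
                             file.path(config$output_dir, image_id),
                             params = list(seed = img_seed, group = g$name,
                                           quench_factor = q))
        files <- c(files, paths)
      }
      seg <- segment_image(img,
                           threshold_method = config$threshold$method,
                           fixed_cqd = config$threshold$fixed_cqd,
                           fixed_nuclear = config$threshold$fixed_nuclear,
                           min_nucleus_area = config$min_nucleus_area,
                           min_cytoplasm_area = config$min_cytoplasm_area,
                           exclude_border = config$exclude_border)
      m <- measure_objects(seg$cyto_labels, seg$cqd_gray,
                           min_area = config$min_cytoplasm_area)
      # the configured (shared) parameter set, not the per-image
      # data-driven thresholds, defines pooling compatibility
      attr(m, "params") <- list(threshold = config$threshold,
                                min_nucleus_area = config$min_nucleus_area,
                                min_cytoplasm_area = config$min_cytoplasm_area,
                                exclude_border = config$exclude_border)
      recs[[image_id]] <- m
      truth_all[[image_id]] <- field$truth
    }
    pooled[[g$name]] <- pool_group(recs, g$name)
    gpath <- file.path(config$output_dir,
                       sprintf("records_%s.csv", g$name))
    write_records_csv(pooled[[g$name]], gpath)
    files <- c(files, gpath)
  }

  all_records <- do.call(rbind, pooled)
  rownames(all_records) <- NULL
  rec_path <- file.path(config$output_dir, "cell_records.csv")
  write_records_csv(all_records, rec_path)

  ctrl_name <- config$groups[[which(vapply(config$groups,
                                           function(g) isTRUE(g$control),
                                           logical(1)))]]$name
  res <- summarize_groups(all_records, control = ctrl_name,
                          alpha = config$stats$alpha,
                          n_bins = config$stats$n_bins,
                          var_equal = config$stats$var_equal,
                          ks_nsim = config$stats$ks_nsim,
                          ks_null_seed = config$stats$ks_null_seed,
                          bonferroni = config$stats$bonferroni)
  tab_path <- file.path(config$output_dir, "group_stats.csv")
  write.csv(res$table, tab_path, row.names = FALSE)
  hist_path <- file.path(config$output_dir, "histograms.csv")
  write.csv(res$histograms, hist_path, row.names = FALSE)
  cfg_path <- file.path(config$output_dir, "config_resolved.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files <- c(files, rec_path, tab_path, hist_path, cfg_path)

  hashes <- tools::md5sum(files)
  manifest <- list(
    config_hash = hash,
    control = ctrl_name,
    n_cells_measured = nrow(all_records),
    files = lapply(seq_along(files),
                   function(i) list(path = basename(files[i]),
                                    md5 = unname(hashes[i]))),
    table = res$table)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  manifest$stats <- res
  manifest$records <- all_records
  manifest$truth <- do.call(rbind, truth_all)
  manifest$config <- config
  invisible(manifest)
}

#' Recompute group statistics from persisted per-cell records
#'
#' Reads the pooled `cell_records.csv` written by [run_pipeline()] and
#' reruns the statistical battery; with the same parameters this
#' reproduces the manifest's p-values bit for bit (records are persisted
#' at full double precision).
#'
#' @param path `cell_records.csv` path.
#' @param control control group name.
#' @param ... passed to [summarize_groups()].
#' @return a [summarize_groups()] result.
#' @export
stats_from_csv <- function(path, control = "control", ...) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  rec$mean_intensity <- as.numeric(rec$mean_intensity)
  summarize_groups(rec, control = control, ...)
}
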