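# File formats: 16-bit grayscale TIFF with a JSON sidecar carrying the
# physical pixel size, localisation CSV tables, scene ground-truth JSON,
# and YAML pipeline configuration.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a rendered image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are stored in units of `scale_max / 65535` (where
#' `scale_max` is the image maximum), so images whose values are exact
#' multiples of that quantum round-trip exactly. Pixel size, channel and
#' scale are recorded in `<path>.json`.
#'
#' @param image A [rendered_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rendered_image"))
  scale_max <- max(image$data, 1e-12)
  tiff::writeTIFF(pmin(pmax(image$data / scale_max, 0), 1), path,
                  bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(pixel_size_nm = image$pixel_size, channel = image$channel,
         scale_max = scale_max),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-channel TIFF as a rendered image
#'
#' The physical pixel size is taken from the JSON sidecar written by
#' [write_image()], or from the `pixel_nm` argument; when neither is
#' available the reader stops and names the remedy. Multi-page TIFFs are
#' rejected with the page count.
#'
#' @param path TIFF path.
#' @param pixel_nm Pixel size override (nm), used when no sidecar exists.
#' @return A [rendered_image()].
#' @export
read_image <- function(path, pixel_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 1L) {
    stop(sprintf("expected a single-image TIFF, found %d pages", length(pages)))
  }
  m <- pages[[1]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("expected a single-channel TIFF")
    m <- m[, , 1]
  }
  side <- sidecar_path(path)
  channel <- "unknown"; scale_max <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixel_nm)) pixel_nm <- meta$pixel_size_nm
    if (!is.null(meta$channel)) channel <- meta$channel
    if (!is.null(meta$scale_max)) scale_max <- meta$scale_max
  }
  if (is.null(pixel_nm)) {
    stop("pixel size not recorded with this TIFF; pass pixel_nm = ",
         "(or --pixel-nm at the command line)")
  }
  rendered_image(m * scale_max, pixel_nm, channel)
}

#' Write a localisation table as CSV
#'
#' Columns written: `x_nm`, `y_nm`, `frame`, `precision_nm`, `intensity`,
#' plus `cluster_id` and the truth columns when present.
#'
#' @param table A `localisation_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localisations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a localisation table from CSV
#'
#' Requires columns `x_nm`, `y_nm`, `frame`; optional `precision_nm`
#' (filled with `default_precision` and flagged when absent) and
#' `intensity` (filled with 1). Non-numeric cells are reported with their
#' row number.
#'
#' @param path CSV path.
#' @param default_precision Precision (nm) used when the column is
#'   missing; default 40.
#' @param field Optional `(width, height)` in nm stored as attributes.
#' @return A `localisation_table` data frame; attribute
#'   `precision_filled` is TRUE when the default was applied.
#' @export
read_localisations <- function(path, default_precision = 40, field = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("x_nm", "y_nm", "frame")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s (expected header x_nm, y_nm, frame)",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c(required, "precision_nm", "intensity"), names(tab))) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
      }
      tab[[col]] <- num
    }
  }
  filled <- FALSE
  if (is.null(tab$precision_nm)) {
    tab$precision_nm <- rep(default_precision, nrow(tab))
    filled <- TRUE
  }
  if (is.null(tab$intensity)) tab$intensity <- rep(1, nrow(tab))
  class(tab) <- c("localisation_table", "data.frame")
  attr(tab, "precision_filled") <- filled
  if (!is.null(field)) {
    attr(tab, "field_width") <- field[1]
    attr(tab, "field_height") <- field[2]
  }
  tab
}

#' Serialise scene ground truth as JSON
#'
#' @param scene A `synthetic_scene`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  obj <- list(
    field_width = scene$field_width, field_height = scene$field_height,
    rng_seed = scene$rng_seed,
    psds = lapply(scene$psds, function(p) list(
      subtype_truth = p$subtype_truth, centre = p$centre,
      nanoclusters = lapply(p$nanoclusters, function(nc) list(
        centre = nc$centre, long_axis = nc$long_axis,
        short_axis = nc$short_axis, orientation = nc$orientation,
        molecule_count = nc$molecule_count)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scene ground truth from JSON
#'
#' @param path JSON path written by [write_scene_json()].
#' @return A `synthetic_scene`.
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  psds <- lapply(obj$psds, function(p) structure(list(
    nanoclusters = lapply(p$nanoclusters, function(nc) list(
      centre = as.numeric(unlist(nc$centre)),
      long_axis = nc$long_axis, short_axis = nc$short_axis,
      orientation = nc$orientation,
      molecule_count = nc$molecule_count)),
    subtype_truth = p$subtype_truth,
    centre = as.numeric(unlist(p$centre))), class = "psd_truth"))
  structure(list(field_width = obj$field_width,
                 field_height = obj$field_height,
                 psds = psds, rng_seed = obj$rng_seed),
            class = "synthetic_scene")
}

#' Pipeline configuration
#'
#' Bundles the simulation, segmentation and PALM parameter sets with a
#' modality, seed and output directory; round-trips losslessly through
#' YAML ([write_config()] / [read_config()]).
#'
#' @param modality `"sted"` or `"palm"`.
#' @param sim A [sim_config()].
#' @param psd_params,nc_params [seg_params()] for the g-STED stages.
#' @param palm A [palm_params()].
#' @param seed Integer seed driving every stochastic stage.
#' @param output_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = c("sted", "palm"),
                            sim = sim_config(),
                            psd_params = sted_psd_params(),
                            nc_params = sted_nc_params(),
                            palm = palm_params(),
                            seed = 1L, output_dir = ".") {
  modality <- match.arg(modality)
  sim <- validate_sim_config(sim)
  stopifnot(inherits(psd_params, "seg_params"),
            inherits(nc_params, "seg_params"),
            inherits(palm, "palm_params"))
  structure(list(modality = modality, sim = sim, psd_params = psd_params,
                 nc_params = nc_params, palm = palm,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- structure(raw$sim, class = "sim_config")
  sim$subtype_mixture <- as.numeric(unlist(sim$subtype_mixture))
  sim$nc_axis_medians <- as.numeric(unlist(sim$nc_axis_medians))
  sim$spacing_interval <- as.numeric(unlist(sim$spacing_interval))
  pipeline_config(
    modality = raw$modality,
    sim = sim,
    psd_params = structure(raw$psd_params, class = "seg_params"),
    nc_params = structure(raw$nc_params, class = "seg_params"),
    palm = structure(raw$palm, class = "palm_params"),
    seed = raw$seed, output_dir = raw$output_dir)
}
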