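# End-to-end pipeline runner: simulate -> render -> segment -> measure ->
# summarise, with full parameter provenance echoed into the output JSON.

# Recursively drop S3 classes so parameter bundles serialise as plain
# JSON/YAML structures.
strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  unclass(x)
}

#' Run the configured pipeline end to end
#'
#' Executes the stages selected by the configuration's modality on a
#' simulated field: scene sampling, rendering (pixel channels or PALM
#' localisations), segmentation, NC-to-PSD assignment, and a field
#' summary. All outputs are deterministic functions of
#' `(config, config$seed)`; every parameter used is echoed into the
#' provenance JSON together with per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param write_outputs Write CSV/JSON/TIFF outputs under
#'   `config$output_dir` (created if needed). When `FALSE` the bundle is
#'   only returned.
#' @return List with `records` (a `psd_records`), `scene`, `summary`
#'   (named list of field-level quantities) and `provenance`.
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  scene <- sample_scene(config$sim, seed)
  if (config$modality == "sted") {
    field <- render_field(scene, config$sim, seed + 1L)
    records <- run_sted_workflow(field$confocal, field$sted,
                                 config$psd_params, config$nc_params)
  } else {
    table <- simulate_palm(scene, config$sim, seed + 1L)
    table <- cluster_localisations(table, config$palm$dbscan_eps,
                                   config$palm$dbscan_min_points)
    records <- run_palm_workflow(table, config$palm)
  }
  fr <- if (nrow(records$psds)) {
    100 * prop.table(table(records$psds$subtype))
  } else table(classify_subtype(1))[0]
  summary <- list(
    modality = config$modality,
    n_psd_truth = length(scene$psds),
    n_psd_detected = records$n_psd_detected,
    n_psd_retained = nrow(records$psds),
    n_nc = nrow(records$ncs),
    excluded_psd_fraction = records$excluded_psd_fraction,
    n_discarded_nc = records$n_discarded_nc,
    median_psd_diameter_nm = if (nrow(records$psds))
      median(records$psds$equivalent_diameter) else NA,
    median_nc_diameter_nm = if (nrow(records$ncs))
      median(records$ncs$equivalent_diameter) else NA,
    mean_nc_per_psd = if (nrow(records$psds))
      mean(records$psds$nc_count) else NA,
    subtype_percent = as.list(setNames(as.numeric(fr), names(fr))))
  provenance <- list(
    package = "nanopsd",
    version = as.character(utils::packageVersion("nanopsd")),
    seed = seed,
    config = strip_classes(config),
    stage_counts = summary)
  if (write_outputs) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_scene_json(scene, out("scene_truth.json"))
    write.csv(records$psds, out("psds.csv"), row.names = FALSE)
    write.csv(records$ncs, out("ncs.csv"), row.names = FALSE)
    jsonlite::write_json(provenance, out("provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = records, scene = scene, summary = summary,
       provenance = provenance)
}
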