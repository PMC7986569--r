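#' Pipeline configuration
#'
#' Central declarative configuration for the tile - filter - score -
#' diagnose pipeline. Defaults are the working values of the method:
#' 300-px patches at x20, 299-px classifier input, background criteria
#' (channel range 20, brightness 220, half the surface), binarization
#' threshold 0.5, cluster size 4 under 4-connectivity, and a simulated
#' classifier at 95% / 99% patch sensitivity / specificity. The `training`
#' block records the fine-tuning hyperparameters of the reference
#' convolutional model for provenance only; no training is performed here.
#'
#' @param patch_size patch side in pixels.
#' @param input_size classifier input side in pixels.
#' @param channel_range_max,brightness_threshold,surface_fraction,bright_is_background
#'   background criteria, see [background_criteria()].
#' @param per_channel_mean normalization flag, see [normalize_patch()].
#' @param threshold score binarization threshold.
#' @param cluster_size minimum qualifying cluster size.
#' @param connectivity 4 or 8.
#' @param sensitivity,specificity,score_dispersion simulated-classifier
#'   operating point, see [simulated_classifier_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` (named list, YAML round-trippable).
#' @export
pipeline_config <- function(patch_size = 300, input_size = 299,
                            channel_range_max = 20,
                            brightness_threshold = 220,
                            surface_fraction = 0.5,
                            bright_is_background = TRUE,
                            per_channel_mean = FALSE,
                            threshold = 0.5, cluster_size = 4,
                            connectivity = 4,
                            sensitivity = 0.95, specificity = 0.99,
                            score_dispersion = 4, seed = 1) {
  cfg <- list(patch_size = patch_size, input_size = input_size,
              channel_range_max = channel_range_max,
              brightness_threshold = brightness_threshold,
              surface_fraction = surface_fraction,
              bright_is_background = bright_is_background,
              per_channel_mean = per_channel_mean,
              threshold = threshold, cluster_size = cluster_size,
              connectivity = connectivity, sensitivity = sensitivity,
              specificity = specificity,
              score_dispersion = score_dispersion, seed = seed,
              training = list(optimizer = "RMSProp",
                              weight_decay = 0.00004, momentum = 0.9,
                              rmsprop_decay = 0.9, learning_rate_initial = 0.01,
                              learning_rate_final = 0.0001,
                              learning_rate_schedule = "exponential",
                              epochs = 150000, batch_size = 64))
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$patch_size >= 1, cfg$input_size >= 1,
            cfg$cluster_size >= 1)
  check_connectivity(cfg$connectivity)
  check_probability(cfg$threshold, "threshold")
  background_criteria(cfg$channel_range_max, cfg$brightness_threshold,
                      cfg$surface_fraction, cfg$bright_is_background)
  simulated_classifier_config(cfg$sensitivity, cfg$specificity,
                              cfg$threshold, cfg$score_dispersion)
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()]. Precedence: explicit overrides > config file >
#' defaults (see [merge_config()]).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  merge_config(pipeline_config(), raw)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Merge configuration overrides
#'
#' Later arguments win: `merge_config(defaults, file_values, flag_values)`
#' implements the flag > file > default precedence. Unknown keys error.
#'
#' @param cfg a `pipeline_config`.
#' @param ... named lists of overrides (NULL entries ignored).
#' @return The merged `pipeline_config`.
#' @export
merge_config <- function(cfg, ...) {
  for (ov in list(...)) {
    if (is.null(ov)) next
    ov <- ov[!vapply(ov, is.null, logical(1))]
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
}

#' Run the full pipeline on simulated slides
#'
#' For each slide: render the truth lattice to a raster, tile it, apply the
#' background filter, score the tissue patches with the simulated
#' classifier, and diagnose by the cluster rule; then group slides into
#' patients and apply the union rule. All stage outputs are written as TSV
#' plus the resolved config (YAML) and a small JSON run manifest carrying
#' the config hash; a rerun with the same config and slides is
#' byte-identical at the TSV level.
#'
#' @param config a [pipeline_config()].
#' @param slides named list of [simulate_truth()] slides.
#' @param patients optional data.frame with columns `slide_id`,
#'   `patient_id`; by default every slide is its own patient.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list: `slide_diagnoses`, `patient_diagnoses`,
#'   `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), slides,
                         patients = NULL, out_dir) {
  if (missing(slides) || length(slides) == 0L)
    stop("pipeline stage 'input': no slides supplied")
  if (is.null(names(slides)) || any(!nzchar(names(slides))))
    names(slides) <- paste0("slide", seq_along(slides))
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  criteria <- background_criteria(config$channel_range_max,
                                  config$brightness_threshold,
                                  config$surface_fraction,
                                  config$bright_is_background)
  clf <- simulated_classifier_config(config$sensitivity, config$specificity,
                                     config$threshold,
                                     config$score_dispersion)
  manifest <- vector("list", length(slides))
  scores <- vector("list", length(slides))
  diags <- vector("list", length(slides))
  for (i in seq_along(slides)) {
    sim <- slides[[i]]
    if (!inherits(sim, "simulated_slide"))
      stop("pipeline stage 'input': slide ", i,
           " is not a simulated_slide")
    sim$slide_id <- names(slides)[i]
    slide <- render_slide(sim, patch_size_px = config$patch_size,
                          seed = config$seed + i)
    grid <- tile_slide(slide, config$patch_size)
    grid <- filter_background(grid, slide, criteria)
    sg <- score_grid(grid, truth = sim$truth, cfg = clf,
                     seed = config$seed + 100000L + i)
    diag <- diagnose_slide(sg, threshold = config$threshold,
                           cluster_size = config$cluster_size,
                           connectivity = config$connectivity)
    manifest[[i]] <- manifest_frame(grid)
    scores[[i]] <- scores_frame(sg)
    diags[[i]] <- diag
  }
  if (is.null(patients))
    patients <- data.frame(slide_id = names(slides),
                           patient_id = names(slides))
  if (!all(c("slide_id", "patient_id") %in% names(patients)))
    stop("pipeline stage 'patient': patients needs slide_id, patient_id")
  missing_map <- setdiff(names(slides), patients$slide_id)
  if (length(missing_map))
    stop("pipeline stage 'patient': unmapped slides: ",
         paste(missing_map, collapse = ", "))
  names(diags) <- names(slides)
  pdiags <- lapply(split(patients$slide_id, patients$patient_id),
                   function(ids) diagnose_patient(diags[ids]))
  for (pid in names(pdiags)) pdiags[[pid]]$patient_id <- pid
  pdiags <- pdiags[order(names(pdiags))]

  files <- list(
    manifest = file.path(out_dir, "patches.tsv"),
    scores = file.path(out_dir, "scores.tsv"),
    slide_calls = file.path(out_dir, "slide_calls.tsv"),
    patient_calls = file.path(out_dir, "patient_calls.tsv"),
    config = file.path(out_dir, "config.yaml"),
    run = file.path(out_dir, "run.json"))
  write.table(do.call(rbind, manifest), files$manifest, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, scores), files$scores, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_slide_calls(diags, files$slide_calls)
  write_patient_calls(pdiags, files$patient_calls)
  write_pipeline_config(config, files$config)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(files$config)),
         n_slides = length(slides), n_patients = length(pdiags),
         package = "patchagg",
         version = as.character(packageVersion("patchagg"))),
    files$run, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(slide_diagnoses = diags, patient_diagnoses = pdiags,
                 files = files))
}
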