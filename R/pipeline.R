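# Pipeline orchestration: one configuration object drives the fixed stage
# order (colour deconvolution -> positive cell detection -> smoothed
# features -> object classification -> dearray -> certification ->
# evaluation), with every random draw flowing from named seeds.

#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults equal to the optimised
#' MLH1 protocol: the H-DAB stain vectors and background of
#' [stain_matrix()], the [detection_params()] settings, 25 um smoothing FWHM
#' restricted to the same base class, a 100-tree forest, dearraying at 0.9 mm
#' pitch with density threshold 5.0 and bounds scale 105.0, and the 75%
#' certification threshold. The configuration round-trips through YAML
#' unchanged.
#'
#' @param stains a [stain_matrix()].
#' @param detection a [detection_params()].
#' @param smoothing_fwhm smoothing FWHM, um.
#' @param smoothing_same_base_class restrict smoothing to the same
#'   Positive/Negative base class.
#' @param classifier list: `ntree`, `mtry` (`NULL` = `sqrt(p)`), `seed`.
#' @param dearray list: `core_diameter`, `density_threshold`, `bounds_scale`,
#'   `rows`, `cols`.
#' @param certification a [certification_params()].
#' @param overrides optional path to a core-override CSV.
#' @param seed master seed for simulation stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stains = stain_matrix(),
                            detection = detection_params(),
                            smoothing_fwhm = 25,
                            smoothing_same_base_class = TRUE,
                            classifier = list(ntree = 100, mtry = NULL,
                                              seed = 42L),
                            dearray = list(core_diameter = 900,
                                           density_threshold = 5.0,
                                           bounds_scale = 105.0,
                                           rows = 9L, cols = 18L),
                            certification = certification_params(),
                            overrides = NULL,
                            seed = 1L) {
  required <- c("core_diameter", "density_threshold", "bounds_scale",
                "rows", "cols")
  miss <- setdiff(required, names(dearray))
  if (length(miss))
    stop("dearray config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("ntree", "seed") %in% names(classifier)))
    stop("classifier config needs 'ntree' and 'seed'", call. = FALSE)
  stopifnot(is_stain_matrix(stains), inherits(detection, "detection_params"),
            inherits(certification, "certification_params"))
  structure(list(stains = stains, detection = detection,
                 smoothing_fwhm = smoothing_fwhm,
                 smoothing_same_base_class = isTRUE(smoothing_same_base_class),
                 classifier = classifier, dearray = dearray,
                 certification = certification, overrides = overrides,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  smoothing FWHM %g um (same base class: %s)\n",
              x$smoothing_fwhm, x$smoothing_same_base_class))
  cat(sprintf("  forest: %d trees, seed %d\n", x$classifier$ntree,
              x$classifier$seed))
  cat(sprintf("  dearray: %g um pitch, density %.1f, bounds scale %.1f\n",
              x$dearray$core_diameter, x$dearray$density_threshold,
              x$dearray$bounds_scale))
  cat(sprintf("  certification threshold %.2f (%s), min cells %d\n",
              x$certification$threshold,
              x$certification$histology_denominator,
              x$certification$min_cells))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write) / the `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- list(
    stains = list(hematoxylin = as.numeric(config$stains$stains[1L, ]),
                  dab = as.numeric(config$stains$stains[2L, ]),
                  background = as.numeric(config$stains$background)),
    detection = unclass(config$detection),
    smoothing = list(fwhm = config$smoothing_fwhm,
                     same_base_class = config$smoothing_same_base_class),
    classifier = config$classifier,
    dearray = config$dearray,
    certification = unclass(config$certification),
    overrides = config$overrides,
    seed = config$seed)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  required <- c("stains", "detection", "smoothing", "classifier", "dearray",
                "certification", "seed")
  miss <- setdiff(required, names(lst))
  if (length(miss))
    stop("config missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pipeline_config(
    stains = stain_matrix(lst$stains$hematoxylin, lst$stains$dab,
                          lst$stains$background),
    detection = do.call(detection_params, lst$detection),
    smoothing_fwhm = lst$smoothing$fwhm,
    smoothing_same_base_class = lst$smoothing$same_base_class,
    classifier = lst$classifier,
    dearray = lst$dearray,
    certification = do.call(certification_params, lst$certification),
    overrides = lst$overrides,
    seed = lst$seed)
}

#' Train the pipeline's tissue classifier from annotated regions
#'
#' Composes the training montage, runs detection and smoothed features on
#' it, labels cells by the annotations, and fits the forest.
#'
#' @param regions list of `list(tile, annotation)` (e.g. from
#'   [simulate_training_regions()]).
#' @param pixel_size um/pixel of the tiles.
#' @param config a [pipeline_config()].
#' @return A `tissue_classifier`.
#' @export
train_pipeline_classifier <- function(regions, pixel_size, config = pipeline_config()) {
  montage <- compose_training_image(lapply(regions, `[[`, "tile"),
                                    lapply(regions, `[[`, "annotation"),
                                    pixel_size,
                                    background_rgb = config$stains$background)
  det <- detect_cells(montage$image, pixel_size, config$stains,
                      config$detection)
  cells <- add_smoothed_features(det$cells, config$smoothing_fwhm,
                                 config$smoothing_same_base_class)
  labels <- label_cells_by_annotation(cells, montage$annotations)
  train_tissue_classifier(cells, labels,
                          ntree = config$classifier$ntree,
                          mtry = config$classifier$mtry,
                          seed = config$classifier$seed)
}

#' Run the full screening pipeline
#'
#' Stage order: dearray the slide, then per valid core colour-deconvolve,
#' detect positive cells, add smoothed features, classify tissue, and
#' finally certify each core and (optionally) evaluate agreement against a
#' reference call table. Deterministic for fixed seeds.
#'
#' @param image a `tma_image` from [render_tma()] (RGB array input is
#'   supported via [dearray()] + [detect_cells()] composed manually).
#' @param model a trained `tissue_classifier`.
#' @param config a [pipeline_config()].
#' @param reference optional reference call table (`core_label`, `call`) for
#'   the agreement report.
#' @param out_dir optional directory for CSV artefacts and a run manifest.
#' @return List: `grid`, `cells` (classified), `calls` (a `core_calls`),
#'   `report` (an `agreement_report` or `NULL`).
#' @export
run_pipeline <- function(image, model, config = pipeline_config(),
                         reference = NULL, out_dir = NULL) {
  stopifnot(inherits(image, "tma_image"), inherits(model, "tissue_classifier"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  grid <- stage("dearray", {
    g <- dearray(image,
                 core_diameter = config$dearray$core_diameter,
                 density_threshold = config$dearray$density_threshold,
                 bounds_scale = config$dearray$bounds_scale,
                 rows = config$dearray$rows, cols = config$dearray$cols)
    if (!is.null(config$overrides)) g <- apply_overrides(g, config$overrides)
    g
  })
  cells <- stage("detection", {
    tp_um <- image$core_spacing
    parts <- vector("list", length(image$tiles))
    for (i in seq_len(image$rows)) for (j in seq_len(image$cols)) {
      k <- (i - 1L) * image$cols + j
      lab <- grid_label(i, j)
      gi <- match(lab, grid$cores$label)
      if (!is.na(gi) && !grid$cores$valid[gi]) next
      d <- detect_cells(image$tiles[[k]], image$pixel_size, config$stains,
                        config$detection,
                        origin_um = c((j - 1L) * tp_um, (i - 1L) * tp_um))
      parts[[k]] <- d$cells
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) stop("no cells detected on any valid core")
    do.call(rbind, parts)
  })
  cells <- stage("smoothed_features", {
    cells <- assign_cells_to_cores(grid, cells)
    add_smoothed_features(cells, config$smoothing_fwhm,
                          config$smoothing_same_base_class)
  })
  cells <- stage("classification", classify_cells(model, cells))
  calls <- stage("certification", certify_all(grid, cells, config$certification))
  report <- if (!is.null(reference))
    stage("evaluation", tryCatch(agreement_report(calls, reference),
                                 error = function(e) NULL))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_grid(grid, file.path(out_dir, "grid.csv"))
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    write.csv(as.data.frame(calls), file.path(out_dir, "calls.csv"),
              row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    manifest <- c(sprintf("tmascreen %s", as.character(utils::packageVersion("tmascreen"))),
                  sprintf("config_md5: %s",
                          unname(tools::md5sum(file.path(out_dir, "config.yaml")))),
                  sprintf("seed: %d", config$seed),
                  sprintf("classifier_seed: %d", config$classifier$seed),
                  sprintf("run_time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  list(grid = grid, cells = cells, calls = calls,
       report = if (!is.null(reference)) report else NULL)
}
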