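# Random-forest tissue-type classification of detected cells.
#
# A small number of annotated training regions is combined into one training
# montage; cells detected there are labelled by the annotation polygon that
# contains them and a random forest is fitted on all raw + smoothed features.
# At application time the forest assigns one of the four tissue classes while
# the Positive/Negative marker base class is carried through unchanged.

#' Compose a training montage from annotated regions
#'
#' Places region tiles in a row-major montage (`nrow = floor(sqrt(n))`)
#' separated by blank background gutters so detections cannot cross regions,
#' and remaps annotation coordinates into the montage frame.
#'
#' @param tiles list of RGB arrays (`h x w x 3`), all at the same pixel size.
#' @param annotations list (one per tile, may be `NULL`) of data.frames or
#'   lists with elements `polygon` (two-column um matrix, tile frame) and
#'   `tissue_class`.
#' @param pixel_size um/pixel shared by all tiles.
#' @param gutter_um width of the blank gutter between tiles.
#' @param background_rgb fill colour for gutters.
#' @return List: `image` (RGB array), `annotations` (list of
#'   `list(polygon, tissue_class)` in montage um coordinates), `offsets_um`
#'   (n x 2 matrix of tile origins), `pixel_size`.
#' @export
compose_training_image <- function(tiles, annotations = NULL, pixel_size,
                                   gutter_um = 50,
                                   background_rgb = c(235, 232, 239)) {
  n <- length(tiles)
  stopifnot(n >= 1L)
  dims <- vapply(tiles, function(t) dim(t)[1:2], integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all tiles must share the same dimensions", call. = FALSE)
  th <- dims[1, 1]; tw <- dims[2, 1]
  g <- as.integer(round(gutter_um / pixel_size))
  nr <- max(1L, floor(sqrt(n)))
  nc <- ceiling(n / nr)
  H <- nr * th + (nr - 1L) * g
  W <- nc * tw + (nc - 1L) * g
  img <- array(0L, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(round(background_rgb[ch]))
  offsets <- matrix(0, n, 2L, dimnames = list(NULL, c("x_um", "y_um")))
  anns <- list()
  for (k in seq_len(n)) {
    r <- (k - 1L) %/% nc; cidx <- (k - 1L) %% nc
    y0 <- r * (th + g); x0 <- cidx * (tw + g)
    img[y0 + seq_len(th), x0 + seq_len(tw), ] <- tiles[[k]]
    offsets[k, ] <- c(x0, y0) * pixel_size
    if (!is.null(annotations) && !is.null(annotations[[k]])) {
      for (a in annotations[[k]]) {
        poly <- a$polygon
        poly[, 1L] <- poly[, 1L] + offsets[k, 1L]
        poly[, 2L] <- poly[, 2L] + offsets[k, 2L]
        anns[[length(anns) + 1L]] <- list(polygon = poly,
                                          tissue_class = a$tissue_class)
      }
    }
  }
  list(image = img, annotations = anns, offsets_um = offsets,
       pixel_size = pixel_size)
}

#' Simulate annotated training regions
#'
#' Renders single-class 500 um x 500 um tissue regions (cycling over the four
#' tissue classes, with both marker-positive and marker-negative variants of
#' the epithelial classes) and annotates each with one full-tile polygon.
#'
#' @param n number of regions (default 14).
#' @param stains a [stain_matrix()].
#' @param pixel_size um/pixel.
#' @param size_um region edge length.
#' @param noise_sd OD noise.
#' @param seed master seed.
#' @return List of `list(tile, cells, annotation)`, ready for
#'   [compose_training_image()].
#' @export
simulate_training_regions <- function(n = 14, stains = stain_matrix(),
                                      pixel_size = 0.5, size_um = 500,
                                      noise_sd = 0.02, seed = 1L) {
  recipes <- list(
    list(class = "NormalEpithelium", pos = 0.95),
    list(class = "Tumour", pos = 0.95),
    list(class = "Tumour", pos = 0.05),
    list(class = "ImmuneInfiltrate", pos = 0.3),
    list(class = "Stroma", pos = 0.1),
    list(class = "NormalEpithelium", pos = 0.95),
    list(class = "Tumour", pos = 0.05))
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rec <- recipes[[(k - 1L) %% length(recipes) + 1L]]
    comp <- setNames(numeric(4), TISSUE_CLASSES); comp[rec$class] <- 1
    sc <- core_scenario(composition = comp,
                        marker_positive_fraction = rec$pos,
                        id = paste0("train_", rec$class))
    rr <- render_region(sc, stains, pixel_size, size_um, size_um, noise_sd,
                        seed = seeds[k])
    margin <- 1
    poly <- cbind(x = c(margin, size_um - margin, size_um - margin, margin),
                  y = c(margin, margin, size_um - margin, size_um - margin))
    out[[k]] <- list(tile = rr$tile, cells = rr$cells,
                     annotation = list(list(polygon = poly,
                                            tissue_class = rec$class)))
  }
  out
}

#' Label cells by containing annotation
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param annotations list of `list(polygon, tissue_class)` in the same frame.
#' @return Character vector of tissue classes (`NA` outside all annotations).
#' @export
label_cells_by_annotation <- function(cells, annotations) {
  lab <- rep(NA_character_, nrow(cells))
  if (nrow(cells) == 0L) return(lab)
  pts <- cbind(cells$x_um, cells$y_um)
  for (a in annotations) {
    inside <- points_in_polygon(pts, a$polygon)
    lab[inside & is.na(lab)] <- a$tissue_class
  }
  lab
}

#' Train the tissue-type random forest
#'
#' Fits a random-trees classifier on every raw and smoothed feature (no
#' feature selection) of the labelled training cells. Refitting with the same
#' data and seed reproduces identical predictions.
#'
#' @param cells training cell table (already passed through
#'   [add_smoothed_features()]).
#' @param labels tissue-class label per cell (`NA` rows are dropped).
#' @param features feature columns; defaults to all raw + smoothed features
#'   present in `cells`.
#' @param ntree number of trees.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed RNG seed for the forest.
#' @param min_per_class classes with fewer training cells trigger a warning.
#' @return Object of class `tissue_classifier`: the fitted forest plus the
#'   feature list, class list, hyperparameters and out-of-bag accuracy.
#' @export
train_tissue_classifier <- function(cells, labels,
                                    features = NULL,
                                    ntree = 100, mtry = NULL, seed = 42L,
                                    min_per_class = 10L) {
  if (is.null(features))
    features <- intersect(c(RAW_FEATURES,
                            grep("^smoothed_", names(cells), value = TRUE)),
                          names(cells))
  keep <- !is.na(labels)
  x <- cells[keep, features, drop = FALSE]
  y <- factor(labels[keep], levels = TISSUE_CLASSES)
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]; y <- y[complete]
  y <- droplevels(y)
  if (nlevels(y) < 2L)
    stop("training set must contain at least two tissue classes", call. = FALSE)
  small <- table(y)[table(y) < min_per_class]
  if (length(small))
    warning(sprintf("class(es) with fewer than %d training cells: %s",
                    min_per_class, paste(names(small), collapse = ", ")),
            call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  forest <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry))
  oob <- 1 - forest$err.rate[ntree, "OOB"]
  structure(list(forest = forest, features = features,
                 classes = levels(y),
                 hyperparameters = list(ntree = ntree, mtry = mtry, seed = seed),
                 oob_accuracy = as.numeric(oob),
                 n_training = length(y)),
            class = "tissue_classifier")
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat(sprintf(paste0("Tissue classifier: random forest, %d trees, mtry %d, ",
                     "%d features\n"),
              x$hyperparameters$ntree, x$hyperparameters$mtry,
              length(x$features)))
  cat(sprintf("  trained on %d cells over classes: %s\n", x$n_training,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  out-of-bag accuracy: %.3f\n", x$oob_accuracy))
  invisible(x)
}

#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(newdata) == 0L)
    return(factor(character(0), levels = object$classes))
  x <- newdata[, object$features, drop = FALSE]
  ok <- stats::complete.cases(x)
  out <- factor(rep(NA_character_, nrow(x)), levels = object$classes)
  if (any(ok)) {
    votes <- predict(object$forest, x[ok, , drop = FALSE], type = "vote",
                     norm.votes = FALSE)
    # majority vote with ties broken by the fixed tissue-class order
    ord <- order(match(colnames(votes), TISSUE_CLASSES))
    votes <- votes[, ord, drop = FALSE]
    out[ok] <- colnames(votes)[max.col(votes, ties.method = "first")]
  }
  out
}

#' Classify cells into composite classes
#'
#' Applies the forest to assign each cell a tissue class and combines it with
#' the unchanged Positive/Negative base class into the composite class (e.g.
#' `Tumour:Positive`). Marker status is never altered by classification.
#'
#' @param model a [train_tissue_classifier()] fit.
#' @param cells cell table with the model's features and `base_class`.
#' @return `cells` with `tissue_class` and `composite_class` columns.
#' @export
classify_cells <- function(model, cells) {
  stopifnot(inherits(model, "tissue_classifier"))
  cells$tissue_class <- as.character(predict(model, cells))
  cells$composite_class <- ifelse(
    is.na(cells$tissue_class) | is.na(cells$base_class), NA_character_,
    paste(cells$tissue_class, cells$base_class, sep = ":"))
  cells
}

#' Save / load a tissue classifier
#'
#' The model is stored as an RDS file with a plain-text sidecar manifest
#' (feature list, hyperparameters, class list) for auditability.
#'
#' @param model a `tissue_classifier`.
#' @param path file path for the model (`.rds`); the manifest is written to
#'   `<path>.manifest.txt`.
#' @return `path` invisibly (save) / the model (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "tissue_classifier"))
  saveRDS(model, path)
  manifest <- c(sprintf("tissue_classifier v1"),
                sprintf("classes: %s", paste(model$classes, collapse = ", ")),
                sprintf("ntree: %d", model$hyperparameters$ntree),
                sprintf("mtry: %d", model$hyperparameters$mtry),
                sprintf("seed: %d", model$hyperparameters$seed),
                sprintf("n_training: %d", model$n_training),
                sprintf("oob_accuracy: %.4f", model$oob_accuracy),
                "features:", paste(" ", model$features))
  writeLines(manifest, paste0(path, ".manifest.txt"))
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tissue_classifier"))
    stop("file does not contain a tissue_classifier", call. = FALSE)
  model
}
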