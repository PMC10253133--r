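# TMA dearraying: find the regular core grid on a whole-slide image, label
# cores A1..I18, and mark cores invalid when too little tissue lies in their
# (scaled) disc. Manual overrides replace the interactive grid adjustment of
# a slide viewer.

#' Binary tissue mask
#'
#' A pixel is tissue iff its total OD (summed over RGB channels) reaches
#' `od_floor`; connected specks smaller than `min_object_um2` are removed.
#'
#' @param img RGB array (0-255).
#' @param pixel_size um/pixel.
#' @param background per-channel white point.
#' @param od_floor total-OD threshold.
#' @param min_object_um2 minimum object area kept, um^2.
#' @return Logical matrix.
#' @export
tissue_mask <- function(img, pixel_size, background = c(235, 232, 239),
                        od_floor = 0.1, min_object_um2 = 100) {
  od <- rgb_to_od(img, background)
  total <- od[, , 1L] + od[, , 2L] + od[, , 3L]
  mask <- total >= od_floor
  if (min_object_um2 > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    n <- max(lab)
    if (n > 0L) {
      areas <- tabulate(lab[lab > 0L], nbins = n) * pixel_size^2
      mask <- matrix(lab > 0L & areas[pmax(lab, 1L)] >= min_object_um2,
                     nrow(mask), ncol(mask))
    }
  }
  mask
}

# Cluster 1-D centre coordinates into grid lines: assign to index by rounding
# against the nominal pitch, then least-squares fit position = a + pitch * idx.
fit_axis <- function(centres, weights, pitch_nominal, n_lines) {
  idx <- round((centres - min(centres)) / pitch_nominal)
  fit <- stats::lm.wfit(cbind(1, idx), centres, weights)
  a <- fit$coefficients[1L]; pitch <- fit$coefficients[2L]
  if (!is.finite(pitch) || pitch <= 0) { pitch <- pitch_nominal; a <- min(centres) }
  # anchor index 0 at the first occupied line; positions for all n_lines
  a + pitch * (seq_len(n_lines) - 1L)
}

#' Dearray a TMA image
#'
#' Finds tissue blobs of roughly core size, estimates the row/column grid by
#' clustering blob centres against the nominal pitch and least-squares
#' fitting a regular grid, fills unoccupied grid intersections, measures each
#' core's tissue fraction inside a disc of diameter
#' `core_diameter * bounds_scale / 100`, and marks a core valid iff
#' `tissue_fraction * 100 >= density_threshold`.
#'
#' @param image a `tma_image` from [render_tma()], or an RGB array.
#' @param pixel_size um/pixel (ignored for `tma_image` input).
#' @param core_diameter nominal grid pitch / core size, um.
#' @param density_threshold minimum tissue percentage of the scaled disc.
#' @param bounds_scale percent scaling of the measured disc (105 = x1.05).
#' @param rows,cols grid shape (rows labelled A.., columns 1..).
#' @param background per-channel white point.
#' @param thumbnail_um target working resolution for the tissue mask, um/px
#'   (dearraying needs no sub-micron detail).
#' @return Object of class `tma_grid`: data.frame `cores` (label, centre,
#'   diameter, tissue_fraction, valid, manually_adjusted) plus fit metadata.
#' @export
dearray <- function(image, pixel_size = NULL, core_diameter = 900,
                    density_threshold = 5.0, bounds_scale = 105.0,
                    rows = 9, cols = 18, background = c(235, 232, 239),
                    thumbnail_um = 4) {
  if (inherits(image, "tma_image")) {
    f <- max(1L, as.integer(round(thumbnail_um / image$pixel_size)))
    tp <- as.integer(round(image$core_spacing / image$pixel_size))
    while (f > 1L && tp %% f != 0L) f <- f - 1L
    th <- tma_thumbnail(image, f)
    img <- th$img; ps <- th$pixel_size
    background <- image$background
  } else {
    if (is.null(pixel_size)) stop("pixel_size required for array input", call. = FALSE)
    img <- image; ps <- pixel_size
  }
  mask <- tissue_mask(img, ps, background)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n) * ps^2
    core_area <- pi * (core_diameter / 2)^2
    big <- which(areas >= 0.02 * core_area)       # blobs of roughly core size
  } else big <- integer(0)
  if (length(big) < 3L)
    stop(sprintf("only %d candidate core blob(s) found; cannot fit a grid",
                 length(big)), call. = FALSE)
  idx <- which(lab > 0L & matrix(lab %in% big, nrow(lab), ncol(lab)))
  l <- lab[idx]
  iy <- ((idx - 1L) %% nrow(lab)) + 1L
  ix <- ((idx - 1L) %/% nrow(lab)) + 1L
  cnt <- tabulate(l)
  keepl <- which(cnt > 0)
  cx <- (rowsum(ix - 0.5, l)[, 1L] / cnt[keepl]) * ps
  cy <- (rowsum(iy - 0.5, l)[, 1L] / cnt[keepl]) * ps
  w <- cnt[keepl]
  col_x <- fit_axis(cx, w, core_diameter, cols)
  row_y <- fit_axis(cy, w, core_diameter, rows)
  disc_r <- core_diameter * (bounds_scale / 100) / 2
  cores <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cores <- cores[order(cores$row, cores$col), ]
  cores$label <- grid_label(cores$row, cores$col)
  cores$x_um <- col_x[cores$col]
  cores$y_um <- row_y[cores$row]
  cores$diameter_um <- core_diameter
  cores$tissue_fraction <- mapply(function(x0, y0)
    disc_tissue_fraction(mask, ps, x0, y0, disc_r), cores$x_um, cores$y_um)
  cores$valid <- cores$tissue_fraction * 100 >= density_threshold
  cores$manually_adjusted <- FALSE
  rownames(cores) <- NULL
  structure(list(cores = cores[, c("label", "row", "col", "x_um", "y_um",
                                   "diameter_um", "tissue_fraction", "valid",
                                   "manually_adjusted")],
                 rows = rows, cols = cols,
                 core_diameter = core_diameter,
                 density_threshold = density_threshold,
                 bounds_scale = bounds_scale,
                 mask = mask, mask_pixel_size = ps),
            class = "tma_grid")
}

disc_tissue_fraction <- function(mask, ps, x0, y0, r) {
  h <- nrow(mask); w <- ncol(mask)
  xs <- max(1L, floor((x0 - r) / ps)):min(w, ceiling((x0 + r) / ps))
  ys <- max(1L, floor((y0 - r) / ps)):min(h, ceiling((y0 + r) / ps))
  if (length(xs) == 0L || length(ys) == 0L) return(0)
  px <- (xs - 0.5) * ps - x0
  py <- (ys - 0.5) * ps - y0
  inside <- outer(py^2, px^2, "+") <= r^2
  m <- mask[ys, xs, drop = FALSE]
  n_in <- sum(inside)
  if (n_in == 0L) return(0)
  sum(m[inside]) / (pi * r^2 / ps^2)
}

#' @export
print.tma_grid <- function(x, ...) {
  cat(sprintf("TMA grid: %d x %d cores (%d valid, %d invalid)\n",
              x$rows, x$cols, sum(x$cores$valid), sum(!x$cores$valid)))
  invisible(x)
}

#' Manually adjust a core
#'
#' Moves a core centre and/or overrides its validity; the tissue fraction is
#' recomputed at a new centre, and the core is flagged as manually adjusted.
#' Idempotent for identical arguments; all other cores are untouched.
#'
#' @param grid a `tma_grid`.
#' @param label core label, e.g. `"B7"`.
#' @param new_centre optional length-2 (x, y) um.
#' @param valid optional logical override.
#' @return The updated `tma_grid`.
#' @export
adjust_core <- function(grid, label, new_centre = NULL, valid = NULL) {
  stopifnot(inherits(grid, "tma_grid"))
  i <- match(label, grid$cores$label)
  if (is.na(i)) stop(sprintf("unknown core label '%s'", label), call. = FALSE)
  if (!is.null(new_centre)) {
    grid$cores$x_um[i] <- new_centre[1L]
    grid$cores$y_um[i] <- new_centre[2L]
    disc_r <- grid$core_diameter * (grid$bounds_scale / 100) / 2
    grid$cores$tissue_fraction[i] <- disc_tissue_fraction(
      grid$mask, grid$mask_pixel_size, new_centre[1L], new_centre[2L], disc_r)
    if (is.null(valid))
      grid$cores$valid[i] <-
        grid$cores$tissue_fraction[i] * 100 >= grid$density_threshold
  }
  if (!is.null(valid)) grid$cores$valid[i] <- isTRUE(valid)
  grid$cores$manually_adjusted[i] <- TRUE
  grid
}

#' Apply a core override table
#'
#' Scripted replacement for interactive grid editing: a CSV with columns
#' `label`, optional `valid` (TRUE/FALSE), optional `x_um`, `y_um`.
#'
#' @param grid a `tma_grid`.
#' @param overrides data.frame or path to a CSV.
#' @return The updated `tma_grid`.
#' @export
apply_overrides <- function(grid, overrides) {
  if (is.character(overrides)) overrides <- read.csv(overrides)
  for (i in seq_len(nrow(overrides))) {
    ctr <- if (all(c("x_um", "y_um") %in% names(overrides)) &&
               is.finite(overrides$x_um[i]))
      c(overrides$x_um[i], overrides$y_um[i]) else NULL
    val <- if ("valid" %in% names(overrides) && !is.na(overrides$valid[i]))
      as.logical(overrides$valid[i]) else NULL
    grid <- adjust_core(grid, overrides$label[i], ctr, val)
  }
  grid
}

#' Assign cells to cores
#'
#' Each cell is assigned to the core whose (scaled) disc contains its
#' centroid; cells outside every valid disc get `NA` and are excluded from
#' certification.
#'
#' @param grid a `tma_grid`.
#' @param cells cell table with `x_um`, `y_um`.
#' @return `cells` with its `core_label` column set.
#' @export
assign_cells_to_cores <- function(grid, cells) {
  stopifnot(inherits(grid, "tma_grid"))
  lab <- rep(NA_character_, nrow(cells))
  if (nrow(cells)) {
    r <- grid$core_diameter * (grid$bounds_scale / 100) / 2
    valid <- grid$cores[grid$cores$valid, ]
    best_d2 <- rep(r^2, nrow(cells))
    for (i in seq_len(nrow(valid))) {
      d2 <- (cells$x_um - valid$x_um[i])^2 + (cells$y_um - valid$y_um[i])^2
      hit <- d2 <= best_d2
      lab[hit] <- valid$label[i]
      best_d2[hit] <- d2[hit]
    }
  }
  cells$core_label <- lab
  cells
}

#' Write / read a TMA grid as CSV
#'
#' @param grid a `tma_grid`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  write.csv(grid$cores, path, row.names = FALSE)
  invisible(path)
}
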