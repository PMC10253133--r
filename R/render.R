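# Brightfield TMA rendering: hard-core nucleus placement, Beer-Lambert stain
# mixing in OD space, additive Gaussian OD noise, 8-bit quantisation.

#' Specification of a simulated TMA slide
#'
#' @param rows,cols grid dimensions (default 9 x 18, rows labelled A-I
#'   top-to-bottom, columns 1-18 left-to-right).
#' @param pixel_size rendering resolution, um/pixel.
#' @param core_spacing grid cell pitch, um.
#' @param tissue_core_diameter diameter of the punched tissue disc, um; must
#'   be smaller than `core_spacing`.
#' @param background_rgb slide background white point.
#' @param scenarios list of [core_scenario()], one per grid position in
#'   row-major order (blanks included as blank scenarios).
#' @param noise_sd standard deviation of the additive per-channel OD noise.
#' @param seed master seed; every random draw in the rendering derives from it.
#' @return Object of class `tma_sim_spec`.
#' @export
tma_sim_spec <- function(rows = 9, cols = 18, pixel_size = 0.5,
                         core_spacing = 900, tissue_core_diameter = 600,
                         background_rgb = c(235, 232, 239),
                         scenarios = NULL, noise_sd = 0.02, seed = 1L) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(core_spacing, "core_spacing", positive = TRUE)
  if (tissue_core_diameter >= core_spacing)
    stop("tissue_core_diameter must be smaller than core_spacing", call. = FALSE)
  if (is.null(scenarios))
    scenarios <- rep(list(scenario_normal_proficient()), rows * cols)
  if (length(scenarios) != rows * cols)
    stop(sprintf("need %d scenarios (rows x cols), got %d",
                 rows * cols, length(scenarios)), call. = FALSE)
  if (!all(vapply(scenarios, inherits, logical(1), "core_scenario")))
    stop("scenarios must all be core_scenario objects", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, core_spacing = core_spacing,
                 tissue_core_diameter = tissue_core_diameter,
                 background_rgb = background_rgb, scenarios = scenarios,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tma_sim_spec")
}

#' @export
print.tma_sim_spec <- function(x, ...) {
  d <- tma_dimensions(x)
  cat(sprintf("TMA simulation spec: %d x %d cores, %g um/px (%d x %d px)\n",
              x$rows, x$cols, x$pixel_size, d[["width_px"]], d[["height_px"]]))
  ids <- vapply(x$scenarios, `[[`, character(1), "id")
  print(table(ids))
  invisible(x)
}

#' Pixel dimensions of the rendered slide
#'
#' @param spec a [tma_sim_spec()].
#' @return Named integer vector `width_px`, `height_px` (width spans columns).
#' @export
tma_dimensions <- function(spec) {
  c(width_px = as.integer(round(spec$cols * spec$core_spacing / spec$pixel_size)),
    height_px = as.integer(round(spec$rows * spec$core_spacing / spec$pixel_size)))
}

grid_label <- function(row, col) paste0(LETTERS[row], col)

# ---- Nucleus placement -----------------------------------------------------

# Hard-core (minimum-distance) dart throwing inside a region. `region` is a
# list: type "disc" (cx, cy, r) or "rect" (w, h), coordinates in um.
# Fails if fewer than `n` points fit within the retry cap (10x target).
place_nuclei <- function(n, region, min_dist) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  pts <- matrix(NA_real_, n, 2L)
  got <- 0L
  attempts <- 0L
  cap <- 10L * n
  md2 <- min_dist^2
  while (got < n && attempts < cap) {
    m <- min(cap - attempts, max(64L, n - got))
    attempts <- attempts + m
    cand <- if (region$type == "disc") {
      rr <- region$r * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
      cbind(region$cx + rr * cos(th), region$cy + rr * sin(th))
    } else {
      cbind(runif(m, 0, region$w), runif(m, 0, region$h))
    }
    for (i in seq_len(m)) {
      if (got >= n) break
      p <- cand[i, ]
      if (got > 0L) {
        d2 <- (pts[seq_len(got), 1L] - p[1L])^2 + (pts[seq_len(got), 2L] - p[2L])^2
        if (min(d2) < md2) next
      }
      got <- got + 1L
      pts[got, ] <- p
    }
  }
  if (got < n)
    stop(sprintf(paste0("hard-core placement infeasible: placed %d of %d nuclei ",
                        "(min distance %.2f um) within the retry cap"),
                 got, n, min_dist), call. = FALSE)
  pts
}

# Class assignment by contiguous angular sectors with widths proportional to
# the composition, rotated by a random offset. Angles are measured about
# `centre` (um).
assign_sectors <- function(pts, centre, composition) {
  comp <- composition / sum(composition)
  rot <- runif(1, 0, 2 * pi)
  ang <- (atan2(pts[, 2L] - centre[2L], pts[, 1L] - centre[1L]) - rot) %% (2 * pi)
  breaks <- c(0, cumsum(comp) * 2 * pi)
  breaks[length(breaks)] <- 2 * pi + 1e-9
  idx <- findInterval(ang, breaks, rightmost.closed = TRUE)
  names(comp)[pmin(pmax(idx, 1L), length(comp))]
}

# DAB patchiness field: low-frequency sinusoidal multiplier, amplitude `amp`,
# wavelength 300 um, phase from the current RNG stream.
patch_multiplier <- function(x, y, amp, wavelength = 300) {
  if (amp <= 0) return(rep(1, length(x)))
  phase <- runif(2, 0, 2 * pi)
  pmax(0, 1 + amp * sin(2 * pi * x / wavelength + phase[1L]) *
             sin(2 * pi * y / wavelength + phase[2L]))
}

# Draw per-cell records for a scenario within `region`; returns a data.frame
# with positions (um, in the tile frame), class, marker status and per-cell
# optical densities and ellipse geometry.
draw_cells <- function(scenario, region, centre) {
  area_mm2 <- if (region$type == "disc") pi * (region$r / 1000)^2
              else (region$w / 1000) * (region$h / 1000)
  n <- rpois(1L, scenario$density * area_mm2)
  mean_radius <- sum(scenario$composition * scenario$radius_mean) /
    sum(scenario$composition)
  pts <- place_nuclei(n, region, min_dist = 1.5 * mean_radius)
  if (n == 0L) return(empty_cells())
  cls <- assign_sectors(pts, centre, scenario$composition)
  r <- pmax(1, rnorm(n, scenario$radius_mean[cls], scenario$radius_sd[cls]))
  asp <- scenario$aspect[cls]
  marker <- runif(n) < scenario$marker_positive_fraction[cls]
  hema <- pmax(0.05, rnorm(n, scenario$hema_od[cls], 0.1 * scenario$hema_od[cls]))
  dab <- ifelse(marker,
                pmax(0, rnorm(n, scenario$dab_od[cls], 0.1 * scenario$dab_od[cls])),
                0)
  dab <- dab * patch_multiplier(pts[, 1L], pts[, 2L], scenario$patchiness)
  data.frame(x_um = pts[, 1L], y_um = pts[, 2L], tissue_class = cls,
             marker_status = ifelse(marker, "Positive", "Negative"),
             radius_um = r, aspect = asp, theta = runif(n, 0, pi),
             hema_od = hema, dab_od = dab, stringsAsFactors = FALSE)
}

empty_cells <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), tissue_class = character(0),
             marker_status = character(0), radius_um = numeric(0),
             aspect = numeric(0), theta = numeric(0), hema_od = numeric(0),
             dab_od = numeric(0), stringsAsFactors = FALSE)
}

# Rasterise cells + tissue background into an 8-bit RGB tile.
# `tissue_idx`: linear indices of tissue pixels (faint haematoxylin base).
render_field <- function(cells, dim_yx, tissue_idx, stains, pixel_size,
                         noise_sd, base_hema_od = 0.1) {
  h_od <- matrix(0, dim_yx[1L], dim_yx[2L])   # nucleus layer
  d_od <- matrix(0, dim_yx[1L], dim_yx[2L])
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      a <- cells$radius_um[i] * sqrt(cells$aspect[i])
      b <- cells$radius_um[i] / sqrt(cells$aspect[i])
      idx <- ellipse_indices(dim_yx, cells$x_um[i], cells$y_um[i], a, b,
                             cells$theta[i], pixel_size)
      if (!length(idx)) next
      if (cells$dab_od[i] > 0) {
        # DAB precipitate texture: dense chromogen deposits locally obscure
        # the counterstain, so a fraction of pixels is DAB-dominant (as on
        # real slides, where this anchors stain-vector estimation)
        dense <- runif(length(idx)) < 0.3
        h_od[idx] <- pmax(h_od[idx],
                          cells$hema_od[i] * ifelse(dense, 0.05, 1))
        d_od[idx] <- pmax(d_od[idx],
                          cells$dab_od[i] * ifelse(dense, 1.3, 0.8))
      } else {
        h_od[idx] <- pmax(h_od[idx], cells$hema_od[i])
      }
    }
  }
  # faint counterstain over cell-free tissue; nuclei occlude it
  if (length(tissue_idx)) {
    bare <- tissue_idx[h_od[tissue_idx] == 0 & d_od[tissue_idx] == 0]
    h_od[bare] <- base_hema_od
  }
  m <- stains$stains
  npx <- prod(dim_yx)
  tile <- array(0L, dim = c(dim_yx, 3L))
  for (ch in 1:3) {
    od <- h_od * m[1L, ch] + d_od * m[2L, ch]
    if (noise_sd > 0) od <- od + rnorm(npx, 0, noise_sd)
    od[od < 0] <- 0
    v <- round(stains$background[ch] * 10^(-od))
    v[v < 0] <- 0; v[v > 255] <- 255
    tile[, , ch] <- as.integer(v)
  }
  tile
}

#' Render one TMA core
#'
#' Places nuclei by a hard-core point process inside the tissue disc, renders
#' each as a class-shaped ellipse with its haematoxylin (and, for
#' marker-positive nuclei, DAB) optical density, adds Gaussian OD noise and
#' quantises to 8-bit RGB via the Beer-Lambert forward model.
#'
#' @param scenario a [core_scenario()].
#' @param stains a [stain_matrix()].
#' @param pixel_size um/pixel.
#' @param tile_um edge length of the square tile (default the 900 um grid
#'   pitch).
#' @param core_diameter_um diameter of the tissue disc.
#' @param noise_sd OD noise standard deviation.
#' @param seed integer seed (the draw is fully reproducible).
#' @return List: `tile` (integer `h x w x 3` RGB array) and `cells`
#'   (per-nucleus ground truth with tile-frame um coordinates).
#' @export
render_core <- function(scenario, stains = stain_matrix(), pixel_size = 0.5,
                        tile_um = 900, core_diameter_um = 600,
                        noise_sd = 0.02, seed = 1L) {
  npx <- as.integer(round(tile_um / pixel_size))
  dim_yx <- c(npx, npx)
  with_seed(seed, {
    if (scenario$blank) {
      tile <- render_field(empty_cells(), dim_yx, integer(0), stains,
                           pixel_size, noise_sd)
      return(list(tile = tile, cells = empty_cells()))
    }
    centre <- c(tile_um / 2, tile_um / 2)
    core_r <- core_diameter_um / 2
    if (scenario$tissue_fill < 1) {
      r <- core_r * sqrt(scenario$tissue_fill)
      off_r <- (core_r - r) * sqrt(runif(1)); off_th <- runif(1, 0, 2 * pi)
      region <- list(type = "disc", cx = centre[1L] + off_r * cos(off_th),
                     cy = centre[2L] + off_r * sin(off_th), r = r)
    } else {
      region <- list(type = "disc", cx = centre[1L], cy = centre[2L], r = core_r)
    }
    cells <- draw_cells(scenario, region, centre)
    xs <- (seq_len(npx) - 0.5) * pixel_size
    inside <- outer((xs - region$cy)^2, (xs - region$cx)^2, "+") <= region$r^2
    tile <- render_field(cells, dim_yx, which(inside), stains, pixel_size,
                         noise_sd)
    list(tile = tile, cells = cells)
  })
}

#' Render a rectangular tissue region
#'
#' Like [render_core()] but fills a width x height rectangle completely with
#' tissue; used to build training tiles.
#'
#' @inheritParams render_core
#' @param width_um,height_um region size in um.
#' @return List: `tile`, `cells` (as in [render_core()]).
#' @export
render_region <- function(scenario, stains = stain_matrix(), pixel_size = 0.5,
                          width_um = 500, height_um = 500, noise_sd = 0.02,
                          seed = 1L) {
  dim_yx <- c(as.integer(round(height_um / pixel_size)),
              as.integer(round(width_um / pixel_size)))
  with_seed(seed, {
    region <- list(type = "rect", w = width_um, h = height_um)
    cells <- if (scenario$blank) empty_cells()
             else draw_cells(scenario, region, c(width_um / 2, height_um / 2))
    tile <- render_field(cells, dim_yx, seq_len(prod(dim_yx)), stains,
                         pixel_size, noise_sd)
    list(tile = tile, cells = cells)
  })
}

#' Render a whole synthetic TMA slide
#'
#' Renders every core of the simulation spec on its regular grid; keeps the
#' slide as per-core tiles (the full 9 x 18 slide at 0.5 um/px would be a
#' 32400 x 16200 pixel image; tiles keep memory bounded) together with full
#' per-cell and per-core ground truth. Deterministic for a fixed spec seed.
#'
#' @param spec a [tma_sim_spec()].
#' @param stains a [stain_matrix()]; its background is taken from the spec.
#' @return Object of class `tma_image`: list with `tiles` (row-major list of
#'   integer RGB arrays), grid geometry, `truth$cells` (absolute um
#'   coordinates, core label, tissue class, marker status) and `truth$cores`
#'   (label, centre, scenario id, expected call, cell count).
#' @export
render_tma <- function(spec, stains = stain_matrix(background = spec$background_rgb)) {
  stopifnot(inherits(spec, "tma_sim_spec"))
  n <- spec$rows * spec$cols
  seeds <- derive_seeds(spec$seed, n)
  tiles <- vector("list", n)
  cell_list <- vector("list", n)
  cores <- vector("list", n)
  for (i in seq_len(spec$rows)) for (j in seq_len(spec$cols)) {
    k <- (i - 1L) * spec$cols + j
    sc <- spec$scenarios[[k]]
    rc <- render_core(sc, stains, spec$pixel_size, spec$core_spacing,
                      spec$tissue_core_diameter, spec$noise_sd, seeds[k])
    tiles[[k]] <- rc$tile
    lab <- grid_label(i, j)
    ox <- (j - 1L) * spec$core_spacing; oy <- (i - 1L) * spec$core_spacing
    if (nrow(rc$cells)) {
      cc <- rc$cells
      cc$x_um <- cc$x_um + ox; cc$y_um <- cc$y_um + oy
      cc$core_label <- lab
      cell_list[[k]] <- cc
    }
    cores[[k]] <- data.frame(
      label = lab, row = i, col = j,
      x_um = ox + spec$core_spacing / 2, y_um = oy + spec$core_spacing / 2,
      scenario = sc$id, blank = sc$blank,
      expected_call = scenario_expected_call(sc),
      n_cells = nrow(rc$cells), stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_list[!vapply(cell_list, is.null, logical(1))])
  if (is.null(cells)) { cells <- empty_cells(); cells$core_label <- character(0) }
  structure(list(tiles = tiles, rows = spec$rows, cols = spec$cols,
                 core_spacing = spec$core_spacing, pixel_size = spec$pixel_size,
                 background = spec$background_rgb,
                 truth = list(cells = cells, cores = do.call(rbind, cores)),
                 spec = spec),
            class = "tma_image")
}

#' @export
print.tma_image <- function(x, ...) {
  cat(sprintf("Synthetic TMA image: %d x %d cores, %g um/px, %d truth cells\n",
              x$rows, x$cols, x$pixel_size, nrow(x$truth$cells)))
  invisible(x)
}

#' Assemble a `tma_image` into a single RGB array
#'
#' @param x a `tma_image` from [render_tma()].
#' @param max_pixels guard against accidental huge allocations.
#' @return Integer `h x w x 3` array.
#' @export
tma_as_array <- function(x, max_pixels = 3e8) {
  stopifnot(inherits(x, "tma_image"))
  tp <- as.integer(round(x$core_spacing / x$pixel_size))
  h <- x$rows * tp; w <- x$cols * tp
  if (as.double(h) * w * 3 > max_pixels)
    stop("assembled image exceeds max_pixels; use tma_thumbnail() instead",
         call. = FALSE)
  out <- array(0L, c(h, w, 3L))
  for (i in seq_len(x$rows)) for (j in seq_len(x$cols)) {
    k <- (i - 1L) * x$cols + j
    out[(i - 1L) * tp + seq_len(tp), (j - 1L) * tp + seq_len(tp), ] <- x$tiles[[k]]
  }
  out
}

# Block-mean downsample of one channel matrix by integer factor.
block_mean <- function(m, f) {
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  a <- colMeans(matrix(m, nrow = f))            # nr x (nc*f) row-blocks
  a <- matrix(a, nrow = nr)
  t(matrix(colMeans(matrix(t(a), nrow = f)), nrow = nc))
}

#' Downsampled whole-slide view
#'
#' Assembles the slide at a coarser resolution by block-averaging each tile;
#' used for dearraying, where sub-micron detail is unnecessary.
#'
#' @param x a `tma_image`.
#' @param factor integer downsampling factor (must divide the tile size).
#' @return List: `img` (numeric `h x w x 3` array, 0-255), `pixel_size` (um).
#' @export
tma_thumbnail <- function(x, factor = 8L) {
  stopifnot(inherits(x, "tma_image"))
  tp <- as.integer(round(x$core_spacing / x$pixel_size))
  if (tp %% factor != 0L) stop("factor must divide the tile size", call. = FALSE)
  tq <- tp %/% factor
  h <- x$rows * tq; w <- x$cols * tq
  out <- array(0, c(h, w, 3L))
  for (i in seq_len(x$rows)) for (j in seq_len(x$cols)) {
    k <- (i - 1L) * x$cols + j
    for (ch in 1:3)
      out[(i - 1L) * tq + seq_len(tq), (j - 1L) * tq + seq_len(tq), ch] <-
        block_mean(x$tiles[[k]][, , ch], factor)
  }
  list(img = out, pixel_size = x$pixel_size * factor)
}

#' Write a synthetic TMA to disk
#'
#' Writes the assembled slide as an 8-bit RGB TIFF plus CSV ground-truth
#' tables (`truth_cells.csv`, `truth_cores.csv`).
#'
#' @param x a `tma_image`.
#' @param dir output directory (created if missing).
#' @param write_image write the TIFF (disable for very large slides).
#' @return `dir`, invisibly.
#' @export
write_tma <- function(x, dir, write_image = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (write_image) {
    arr <- tma_as_array(x)
    tiff::writeTIFF(arr / 255, file.path(dir, "slide.tif"))
  }
  cells <- x$truth$cells
  write.csv(cells[, intersect(c("x_um", "y_um", "core_label", "tissue_class",
                                "marker_status"), names(cells))],
            file.path(dir, "truth_cells.csv"), row.names = FALSE)
  write.csv(x$truth$cores, file.path(dir, "truth_cores.csv"), row.names = FALSE)
  invisible(dir)
}

#' Study-style scenario layout for a 9 x 18 TMA
#'
#' Builds the default full-slide condition: 74 unambiguous cores (30 normal
#' mucosa, 26 marker-proficient tumours, 18 marker-deficient tumours), 25
#' ambiguous cores in the five flag categories (16 histology-ambiguous:
#' scant/atypical/immune-rich/normal-mucosa, 4 each; 8 with weak or patchy
#' staining; 1 ambiguous in both), 15 orientation blanks and 48 sub-threshold
#' scant cores that the dearrayer should invalidate. Positions are permuted
#' deterministically from the seed, re-drawing until every grid row and
#' column contains at least two full-tissue cores (so the dearrayer's grid
#' fit is well posed).
#'
#' @param seed integer seed for the position permutation.
#' @return List of 162 [core_scenario()]s in row-major grid order.
#' @export
tma_study_layout <- function(seed = 1L) {
  scen <- c(replicate(30, scenario_normal_proficient(), simplify = FALSE),
            replicate(26, scenario_tumour_proficient(), simplify = FALSE),
            replicate(18, scenario_tumour_deficient(), simplify = FALSE),
            replicate(4, scenario_scant_mixed(), simplify = FALSE),
            replicate(4, scenario_atypical_tumour(), simplify = FALSE),
            replicate(4, scenario_immune_rich(), simplify = FALSE),
            replicate(4, scenario_normal_mucosa(), simplify = FALSE),
            replicate(8, scenario_patchy_stain(), simplify = FALSE),
            replicate(1, scenario_immune_patchy(), simplify = FALSE),
            replicate(15, scenario_blank(), simplify = FALSE),
            replicate(48, scenario_excluded_scant(), simplify = FALSE))
  stopifnot(length(scen) == 162L)
  strong <- vapply(scen, function(s) !s$blank && s$tissue_fill >= 0.2, logical(1))
  with_seed(seed, {
    repeat {
      ord <- sample.int(162L)
      m <- matrix(strong[ord], nrow = 9L, ncol = 18L, byrow = TRUE)
      if (min(rowSums(m)) >= 2L && min(colSums(m)) >= 2L) break
    }
  })
  scen[ord]
}
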