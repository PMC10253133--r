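# Optical-density transform, stain matrices and colour deconvolution.
#
# Brightfield absorbance follows Beer-Lambert: per channel,
#   I = I0 * 10^(-OD),  OD = sum over stains of concentration * unit OD vector.
# Deconvolution inverts this 3x3 linear mixing model per pixel.

#' Stain matrix for haematoxylin/DAB colour deconvolution
#'
#' Bundles unit optical-density (OD) RGB vectors for haematoxylin and DAB, a
#' residual vector orthogonal to both, and the background (white-point) RGB.
#' Defaults are the H-DAB vectors and background used throughout the package:
#' haematoxylin (0.67253, 0.56452, 0.47856), DAB (0.25141, 0.41193, 0.87585),
#' background (235, 232, 239).
#'
#' @param hematoxylin length-3 numeric, haematoxylin OD direction (RGB order).
#' @param dab length-3 numeric, DAB OD direction.
#' @param background length-3 numeric in (0, 255], per-channel white point.
#' @return An object of class `stain_matrix`: list with `stains` (3x3 matrix,
#'   rows Hematoxylin/DAB/Residual, columns R/G/B, each row unit norm) and
#'   `background`.
#' @export
stain_matrix <- function(hematoxylin = c(0.67253, 0.56452, 0.47856),
                         dab = c(0.25141, 0.41193, 0.87585),
                         background = c(235, 232, 239)) {
  for (v in list(hematoxylin, dab)) {
    if (length(v) != 3L || !all(is.finite(v)))
      stop("stain vectors must be finite length-3 numerics", call. = FALSE)
    if (sqrt(sum(v^2)) < 1e-8) stop("stain vector has zero norm", call. = FALSE)
  }
  if (length(background) != 3L || any(background <= 0) || any(background > 255))
    stop("background channels must lie in (0, 255]", call. = FALSE)
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6)
    stop("hematoxylin and DAB vectors are collinear; matrix not invertible",
         call. = FALSE)
  r <- r / nr
  m <- rbind(Hematoxylin = h, DAB = d, Residual = r)
  colnames(m) <- c("R", "G", "B")
  structure(list(stains = m, background = as.numeric(background)),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("Stain matrix (unit OD vectors, RGB order)\n")
  print(round(x$stains, 5))
  cat("Background RGB:", paste(round(x$background, 1), collapse = ", "), "\n")
  invisible(x)
}

is_stain_matrix <- function(x) inherits(x, "stain_matrix")

#' RGB image to optical density
#'
#' Per channel, `OD = -log10(max(value, 1) / background)`, clamped at zero for
#' values brighter than the background. Accepts an `h x w x 3` array or an
#' `n x 3` matrix of 8-bit values.
#'
#' @param img RGB values, 0-255.
#' @param background per-channel white point (length-3, > 0).
#' @return Array or matrix of the same shape holding OD values (all >= 0).
#' @export
rgb_to_od <- function(img, background = c(235, 232, 239)) {
  if (length(background) != 3L || any(background <= 0))
    stop("background channels must be > 0", call. = FALSE)
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)) || d[length(d)] != 3L)
    stop("img must be an h x w x 3 array or n x 3 matrix", call. = FALSE)
  v <- pmax(as.numeric(img), 1)
  bg <- if (length(d) == 3L) rep(background, each = d[1L] * d[2L])
        else rep(background, each = d[1L])
  od <- -log10(v / bg)
  od[od < 0] <- 0
  array(od, dim = d)
}

# OD from stain concentrations: conc is n x 3 (H, DAB, residual) -> n x 3 OD.
concentrations_to_od <- function(conc, stains) {
  conc %*% stains$stains
}

#' Compose RGB pixels from stain concentrations
#'
#' The forward Beer-Lambert model: each channel is
#' `background * 10^(-sum(stain_vector * concentration))`, rounded and clamped
#' to 0-255. This is the exact inverse of [deconvolve()] up to 8-bit
#' quantisation.
#'
#' @param concentrations length-3 numeric (hematoxylin, DAB, residual) or an
#'   `n x 3` matrix of non-negative stain amounts in OD units.
#' @param stains a [stain_matrix()].
#' @return Integer RGB values matching the input shape (length 3 or `n x 3`).
#' @export
compose_pixel <- function(concentrations, stains = stain_matrix()) {
  stopifnot(is_stain_matrix(stains))
  conc <- if (is.null(dim(concentrations))) matrix(concentrations, nrow = 1L)
          else as.matrix(concentrations)
  if (ncol(conc) != 3L) stop("concentrations must have 3 stain columns", call. = FALSE)
  if (any(conc < 0)) stop("stain concentrations must be non-negative", call. = FALSE)
  od <- concentrations_to_od(conc, stains)
  rgb <- round(rep(stains$background, each = nrow(conc)) * 10^(-od))
  rgb[rgb < 0] <- 0; rgb[rgb > 255] <- 255
  out <- matrix(as.integer(rgb), nrow = nrow(conc), ncol = 3L,
                dimnames = list(NULL, c("R", "G", "B")))
  if (is.null(dim(concentrations))) out[1L, ] else out
}

#' Colour deconvolution
#'
#' Solves the per-pixel 3x3 linear system `OD = t(M) %*% c` for the stain
#' concentrations `c`, where rows of `M` are the unit stain vectors. Negative
#' solutions are clamped to zero (stain amounts are physical quantities).
#'
#' @param od 3-channel OD array (`h x w x 3`) or `n x 3` matrix, e.g. from
#'   [rgb_to_od()].
#' @param stains a [stain_matrix()].
#' @return A list of per-stain OD images/vectors: `hematoxylin`, `dab`,
#'   `residual`, each `h x w` (or length `n`).
#' @export
deconvolve <- function(od, stains = stain_matrix()) {
  stopifnot(is_stain_matrix(stains))
  m <- stains$stains
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular", call. = FALSE)
  d <- dim(od)
  flat <- if (length(d) == 3L) matrix(od, ncol = 3L) else as.matrix(od)
  conc <- unname(flat %*% solve(m))
  conc[conc < 0] <- 0
  shape <- function(v) if (length(d) == 3L) matrix(v, d[1L], d[2L]) else v
  list(hematoxylin = shape(conc[, 1L]),
       dab = shape(conc[, 2L]),
       residual = shape(conc[, 3L]))
}

#' Estimate stain vectors from an image
#'
#' Recovers the two dominant stain directions from the OD point cloud of
#' stained pixels: pixels with total OD above `od_floor` are projected onto
#' the plane of their top two principal components, and the directions at the
#' extreme angular percentiles are taken as the stain vectors (robust extreme
#' directions of the cloud). The residual is the normalised cross product.
#' The stain with the larger red-channel OD loading is labelled haematoxylin
#' (haematoxylin absorbs red strongly, DAB absorbs blue strongly).
#'
#' @param img RGB array (`h x w x 3`, 0-255).
#' @param background per-channel white point.
#' @param od_floor minimum total OD for a pixel to count as stained
#'   (default 0.3: comfortably above counterstain background and noise).
#' @param percentile angular percentile for the extreme directions (default 1,
#'   meaning the 1st and 99th percentile angles).
#' @param min_pixels minimum number of stained pixels required.
#' @return A [stain_matrix()].
#' @export
estimate_stain_vectors <- function(img, background = c(235, 232, 239),
                                   od_floor = 0.3, percentile = 1,
                                   min_pixels = 200) {
  od <- rgb_to_od(img, background)
  flat <- matrix(od, ncol = 3L)
  keep <- rowSums(flat) >= od_floor
  if (sum(keep) < min_pixels)
    stop(sprintf("only %d stained pixels above OD floor %.3g (need >= %d)",
                 sum(keep), od_floor, min_pixels), call. = FALSE)
  x <- flat[keep, , drop = FALSE]
  # plane of the two dominant directions (uncentred PCA: directions from origin)
  sv <- svd(x, nu = 0, nv = 2)
  v <- sv$v
  proj <- x %*% v
  # orient the basis so the bulk of the cloud has positive first coordinate
  if (median(proj[, 1L]) < 0) { v[, 1L] <- -v[, 1L]; proj[, 1L] <- -proj[, 1L] }
  ang <- atan2(proj[, 2L], proj[, 1L])
  lo <- quantile(ang, percentile / 100, names = FALSE)
  hi <- quantile(ang, 1 - percentile / 100, names = FALSE)
  if ((hi - lo) < (2 * pi / 180))
    stop("angular spread of stained pixels < 2 degrees: only one stain present?",
         call. = FALSE)
  # Initial direction of each stain = mean OD vector of the extreme angular
  # tail; then refine by angular mean-shift (window 4 degrees, 3 iterations).
  # Pure-stain pixels form clusters with symmetric noise, so the local mean
  # is an unbiased estimate of the stain direction, unlike a raw quantile
  # direction which sits in the noise tail.
  tail_angle <- function(rows) {
    u <- colMeans(x[rows, , drop = FALSE])
    p <- as.numeric(t(v) %*% u)
    atan2(p[2L], p[1L])
  }
  mean_shift <- function(a, window = 4 * pi / 180, iters = 3L) {
    for (i in seq_len(iters)) {
      rows <- abs(ang - a) <= window
      if (!any(rows)) break
      a <- tail_angle(rows)
    }
    a
  }
  to_vec <- function(a) {
    u <- as.numeric(v %*% c(cos(a), sin(a)))
    u <- pmax(u, 0)                  # OD loadings are physical (non-negative)
    u / sqrt(sum(u^2))
  }
  s1 <- to_vec(mean_shift(tail_angle(ang <= lo)))
  s2 <- to_vec(mean_shift(tail_angle(ang >= hi)))
  # haematoxylin absorbs red more than DAB does
  if (s1[1L] >= s2[1L]) stain_matrix(s1, s2, background)
  else stain_matrix(s2, s1, background)
}
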