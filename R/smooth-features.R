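# Gaussian-smoothed neighbourhood features: each cell's raw features are
# averaged over nearby cells with Gaussian distance weights, optionally
# restricted to cells sharing the Positive/Negative base class. These
# context features let the object classifier see tissue architecture, not
# just single-cell morphology.

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))   # 2.3548...

#' Add Gaussian-smoothed neighbourhood features
#'
#' For each cell i and raw feature f,
#' `smoothed_f(i) = sum_j w_ij f(j) / sum_j w_ij`,
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))`, `sigma = fwhm / 2.3548`, summing over
#' cells j (including i itself) within `3 sigma` of i. With
#' `same_base_class = TRUE` (the default) only neighbours sharing i's
#' Positive/Negative base class contribute, so positive and negative
#' populations are smoothed separately. Smoothing never runs across cores:
#' cells are grouped by `core_label` when present. A cell with no eligible
#' neighbour keeps its raw value. Each smoothed feature is appended as
#' `smoothed_<fwhm>um_<feature>`.
#'
#' @param cells cell table with `x_um`, `y_um`, the feature columns, and
#'   `base_class` (required when `same_base_class` is `TRUE`).
#' @param fwhm full width at half maximum of the Gaussian, um.
#' @param same_base_class restrict the neighbourhood to the same base class.
#' @param features character vector of columns to smooth (default: all raw
#'   morphology/intensity features present).
#' @return `cells` with the smoothed columns appended.
#' @export
add_smoothed_features <- function(cells, fwhm = 25, same_base_class = TRUE,
                                  features = intersect(RAW_FEATURES, names(cells))) {
  stopifnot_scalar(fwhm, "fwhm", positive = TRUE)
  if (!all(c("x_um", "y_um") %in% names(cells)))
    stop("cells must have x_um and y_um centroids", call. = FALSE)
  if (length(features) == 0L) stop("no features to smooth", call. = FALSE)
  out_names <- paste0("smoothed_", fwhm, "um_", features)
  for (nm in out_names) cells[[nm]] <- NA_real_
  n <- nrow(cells)
  if (n == 0L) return(cells)
  sigma <- fwhm / FWHM_TO_SIGMA
  cutoff <- 3 * sigma
  group <- if ("core_label" %in% names(cells)) as.character(cells$core_label)
           else rep("all", n)
  if (same_base_class) {
    if (!"base_class" %in% names(cells))
      stop("same_base_class = TRUE requires a base_class column", call. = FALSE)
    group <- paste(group, as.character(cells$base_class))
  }
  fm <- as.matrix(cells[, features, drop = FALSE])
  for (g in unique(group)) {
    rows <- which(group == g)
    sm <- smooth_group(cells$x_um[rows], cells$y_um[rows],
                       fm[rows, , drop = FALSE], sigma, cutoff)
    for (k in seq_along(features)) cells[rows, out_names[k]] <- sm[, k]
  }
  # cells with no eligible neighbours (e.g. NA base class groups) keep raw
  for (k in seq_along(features)) {
    nm <- out_names[k]
    miss <- is.na(cells[[nm]]) & !is.na(fm[, k])
    cells[[nm]][miss] <- fm[miss, k]
  }
  cells
}

# Dense pairwise smoothing within one group (a core x base-class stratum);
# O(n^2) in blocks, fine at per-core cell counts.
smooth_group <- function(x, y, fm, sigma, cutoff) {
  n <- length(x)
  out <- matrix(NA_real_, n, ncol(fm))
  block <- max(1L, floor(4e6 / max(n, 1L)))
  ok <- !is.na(rowSums(fm))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(x[rows], x, "-")^2 + outer(y[rows], y, "-")^2
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > cutoff^2] <- 0
    w[, !ok] <- 0
    tot <- rowSums(w)
    good <- tot > 0
    fm0 <- fm; fm0[!ok, ] <- 0
    out[rows[good], ] <- (w[good, , drop = FALSE] %*% fm0) / tot[good]
  }
  # fall back to the raw value where no neighbour (incl. self) was usable
  none <- is.na(out[, 1L])
  out[none, ] <- fm[none, ]
  out
}

#' Names of the smoothed-feature columns
#'
#' @param fwhm smoothing FWHM in um.
#' @param features raw feature names.
#' @return Character vector of column names produced by
#'   [add_smoothed_features()].
#' @export
smoothed_feature_names <- function(fwhm = 25, features = RAW_FEATURES) {
  paste0("smoothed_", fwhm, "um_", features)
}
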