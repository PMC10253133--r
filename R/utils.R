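# Internal geometry and raster helpers shared across modules.

#' @importFrom stats rnorm rpois runif quantile median setNames qbeta predict
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tissue class labels
#'
#' The four tissue classes the object classifier distinguishes, in the fixed
#' order used for tie-breaking: normal epithelium, tumour, immune infiltrate,
#' stroma.
#' @export
TISSUE_CLASSES <- c("NormalEpithelium", "Tumour", "ImmuneInfiltrate", "Stroma")

#' @rdname TISSUE_CLASSES
#' @export
BASE_CLASSES <- c("Positive", "Negative")

EPITHELIAL_CLASSES <- c("NormalEpithelium", "Tumour")

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Area of a closed polygon (shoelace); vertices as two-column matrix.
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# One iteration of Chaikin corner cutting on a closed polygon.
chaikin <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(xy)
  nxt <- xy[c(2:n, 1L), , drop = FALSE]
  q <- 0.75 * xy + 0.25 * nxt
  r <- 0.25 * xy + 0.75 * nxt
  out <- matrix(0, 2L * n, 2L)
  out[seq(1L, 2L * n, by = 2L), ] <- q
  out[seq(2L, 2L * n, by = 2L), ] <- r
  out
}

# Points-in-polygon via mgcv's winding-number test.
points_in_polygon <- function(pts, poly) {
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(rbind(as.matrix(poly), c(NA, NA)), as.matrix(pts))
}

# Rasterise a filled ellipse onto value matrix `m` (indexed [row = y, col = x],
# pixel centres at (ix - 0.5, iy - 0.5) * pixel_size): returns linear indices.
ellipse_indices <- function(dim_yx, cx, cy, a, b, theta, pixel_size) {
  h <- dim_yx[1L]; w <- dim_yx[2L]
  r <- max(a, b)
  x0 <- max(1L, floor((cx - r) / pixel_size)); x1 <- min(w, ceiling((cx + r) / pixel_size))
  y0 <- max(1L, floor((cy - r) / pixel_size)); y1 <- min(h, ceiling((cy + r) / pixel_size))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- (x0:x1 - 0.5) * pixel_size - cx
  ys <- (y0:y1 - 0.5) * pixel_size - cy
  ct <- cos(theta); st <- sin(theta)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  u <- (X * ct + Y * st) / a
  v <- (-X * st + Y * ct) / b
  inside <- which(u^2 + v^2 <= 1)
  if (length(inside) == 0L) return(integer(0))
  iy <- ((inside - 1L) %% length(ys)) + y0
  ix <- ((inside - 1L) %/% length(ys)) + x0
  (ix - 1L) * h + iy
}

# Deterministic per-unit seeds derived from one master seed.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Run expr with a local RNG stream; outer RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
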