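# Internal helpers shared across the pipeline.

#' @importFrom stats fft rnorm runif median mad sd quantile setNames
#' @importFrom utils head
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Makes every generator a pure function of its arguments including `seed`.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Rec. 601 luma on a HxWx3 array (0..255) -> HxW gray matrix (0..255).
# The weighting is part of the gray-level provenance; do not change silently.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

rgb_to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  luma_cpp(img, dim(img)[1], dim(img)[2])
}

# Edge-aware mean filter with a (2r+1)^2 window via an integral image; O(n)
# regardless of radius, which matters on whole-slide rasters.
box_blur <- function(m, r) {
  if (r < 1) return(m)
  box_blur_cpp(m, as.integer(r))
}

# Bilinear interpolation of values `z` (length(rx) x length(cx) grid at row
# coords rx, col coords cx) onto the integer pixel grid 1..nr, 1..nc, with
# flat extrapolation at the borders.
interp_grid <- function(z, rx, cx, nr, nc) {
  ri <- findInterval(seq_len(nr), rx, all.inside = TRUE)
  ci <- findInterval(seq_len(nc), cx, all.inside = TRUE)
  fr <- (seq_len(nr) - rx[ri]) / (rx[ri + 1L] - rx[ri])
  fc <- (seq_len(nc) - cx[ci]) / (cx[ci + 1L] - cx[ci])
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  z00 <- z[cbind(rep(ri, nc), rep(ci, each = nr))]
  z10 <- z[cbind(rep(ri + 1L, nc), rep(ci, each = nr))]
  z01 <- z[cbind(rep(ri, nc), rep(ci + 1L, each = nr))]
  z11 <- z[cbind(rep(ri + 1L, nc), rep(ci + 1L, each = nr))]
  (1 - fr) %o% (1 - fc) * matrix(z00, nr, nc) +
    fr %o% (1 - fc) * matrix(z10, nr, nc) +
    (1 - fr) %o% fc * matrix(z01, nr, nc) +
    fr %o% fc * matrix(z11, nr, nc)
}

# Smooth random field in [0,1]: coarse iid normals, blurred at coarse scale,
# bilinearly upsampled. Cheap at any output size.
smooth_field <- function(nr, nc, coarse = 24L, coarse_blur = 2L) {
  g <- matrix(rnorm(coarse * coarse), coarse, coarse)
  g <- box_blur(g, coarse_blur)
  up <- interp_grid(g, seq(1, nr, length.out = coarse),
                    seq(1, nc, length.out = coarse), nr, nc)
  rng <- range(up)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, nr, nc))
  (up - rng[1]) / diff(rng)
}

# Scanline rasterization of a closed polygon into a logical matrix.
# Vertices are 0-based pixel coordinates (x = column, y = row), origin top-left;
# a pixel (r, c) is inside if its center (c - 1 + 0.5, r - 1 + 0.5) is inside
# the polygon under the even-odd rule. No geometry package in the stack does
# this, hence hand-rolled and oracle-tested against point-in-polygon.
rasterize_polygon <- function(xy, nrow, ncol) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L, nrow(xy) >= 3L)
  out <- matrix(FALSE, nrow, ncol)
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  ymin <- max(1L, floor(min(y) + 0.5) + 1L)
  ymax <- min(nrow, ceiling(max(y) - 0.5) + 1L)
  if (ymin > ymax) return(out)
  for (r in ymin:ymax) {
    yc <- r - 0.5                      # pixel-center y in 0-based coords
    cross <- numeric(0)
    for (k in seq_len(n)) {
      y1 <- y[k]; y2 <- y[j[k]]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        t <- (yc - y1) / (y2 - y1)
        cross <- c(cross, x[k] + t * (x[j[k]] - x[k]))
      }
    }
    if (length(cross) < 2L) next
    cross <- sort(cross)
    for (k in seq(1L, length(cross) - 1L, by = 2L)) {
      c1 <- max(1L, floor(cross[k] + 0.5) + 1L)
      c2 <- min(ncol, ceiling(cross[k + 1L] - 0.5))
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

# Union rasterization of a list of polygons (each an n x 2 matrix).
rasterize_polygons <- function(polys, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  for (p in polys) m <- m | rasterize_polygon(p, nrow, ncol)
  m
}

# Translate a matrix or HxWx3 array by integer (dy, dx), filling with `fill`.
translate_image <- function(img, dy, dx, fill = 0) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  d <- dim(img)
  if (length(d) == 2L) return(translate_matrix_cpp(img, dy, dx, fill))
  out <- array(fill, dim = d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- translate_matrix_cpp(img[, , ch], dy, dx, fill)
  out
}
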