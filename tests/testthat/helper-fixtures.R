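# Shared fixtures: everything is generated in code at test time.

# Small phantom with all features (clusters, singles, stroma, exclusions).
small_phantom <- function(seed = 1, ...) {
  generate_phantom(canvas_size = c(512L, 512L), n_clusters = 1L,
                   cells_per_cluster = 7L, n_singles = 5L,
                   cluster_spread = 45, n_exclusions = 1L, seed = seed, ...)
}

# Slide scan wrapped around a gray-level matrix (all three channels equal).
scan_from_gray <- function(gray, pixel_size = 1, marker = "NRF2") {
  img <- array(0, dim = c(nrow(gray), ncol(gray), 3L))
  img[, , 1] <- gray; img[, , 2] <- gray; img[, , 3] <- gray
  slide_scan(img, pixel_size = pixel_size, marker = marker)
}

# Uniform white tile set.
white_tiles <- function(n_tiles = 4L, shape = c(64L, 64L)) {
  tiles <- replicate(n_tiles, array(255, dim = c(shape, 3L)), simplify = FALSE)
  tile_set(tiles, c(2L, n_tiles / 2L), overlap = 0L, pixel_size = 1,
           marker = "CK7")
}

# Independent even-odd point-in-polygon test (ray casting), used as the
# oracle for the scanline rasterizer.
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# Independent Rec. 601 luma (oracle for the compiled kernel).
luma_oracle <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Printed band definition, restated independently of density_band().
band_oracle <- function(f) {
  if (f == 0) "maternal" else if (f <= 0.5) "low" else "high"
}
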